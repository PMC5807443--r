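## Fluxomics stage: PCA bi-plot of isotopomer fractional abundances and
## an empirical-Bayes moderated per-feature group test. Features are
## (metabolite, isotopomer) columns, not metabolite aggregates.

flux_feature_matrix <- function(table) {
  if (is.data.frame(table)) {
    num <- vapply(table, is.numeric, logical(1))
    x <- as.matrix(table[, num, drop = FALSE])
    genotype <- if (!is.null(table$genotype)) as.character(table$genotype)
    else rep(NA_character_, nrow(x))
  } else {
    x <- as.matrix(table)
    genotype <- rep(NA_character_, nrow(x))
  }
  list(x = x, genotype = genotype)
}

#' PCA bi-plot of an isotopomer table
#'
#' Column-centered (optionally unit-scaled) principal component analysis
#' via singular value decomposition. Loadings columns are orthonormal;
#' each component's sign is fixed so its largest-magnitude loading is
#' positive, making results deterministic across runs. Unit scaling is
#' off by default: fractional abundances are already commensurate.
#'
#' @param table an isotopomer table (data.frame with a `genotype` column
#'   plus numeric feature columns) or a plain numeric matrix.
#' @param scale unit-scale features; zero-variance features are then
#'   dropped with a warning.
#' @return object of class `"pca_biplot"`: `scores` (samples x
#'   components), `loadings` (features x components),
#'   `variance_explained`, `sdev`, `genotype`.
#' @export
pca_biplot <- function(table, scale = FALSE) {
  fm <- flux_feature_matrix(table)
  x <- fm$x
  if (nrow(x) < 3) stop("PCA needs >= 3 samples")
  v <- apply(x, 2, stats::var)
  if (scale && any(v == 0)) {
    warning(sum(v == 0), " zero-variance feature(s) dropped before scaling")
    x <- x[, v > 0, drop = FALSE]
    v <- v[v > 0]
  }
  if (sum(v > 0) < 2) stop("need >= 2 features with nonzero variance")
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(list(scores = scores, loadings = rotation,
                 variance_explained = pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev, genotype = fm$genotype,
                 center = pc$center,
                 scale = if (isTRUE(scale)) pc$scale else NULL),
            class = "pca_biplot")
}

#' Rank metabolites by their loading on a principal component
#'
#' Aggregates per-feature loadings to the metabolite level by the
#' maximum absolute loading over that metabolite's isotopomer columns;
#' used to read which metabolites drive the separation in the bi-plot.
#'
#' @param pb a [pca_biplot()] result.
#' @param component which component (default 1).
#' @return data.frame sorted by decreasing `max_abs_loading` with
#'   columns `metabolite`, `max_abs_loading`, `top_feature`.
#' @export
loading_ranks <- function(pb, component = 1) {
  l <- pb$loadings[, component]
  met <- feature_metabolite(names(l))
  res <- lapply(split(seq_along(l), met), function(idx) {
    j <- idx[which.max(abs(l[idx]))]
    data.frame(metabolite = met[j], max_abs_loading = abs(l[j]),
               top_feature = names(l)[j])
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$max_abs_loading), ]
  rownames(out) <- NULL
  out
}

#' Mean silhouette width of a two-group labelling on PCA scores
#'
#' Simple Euclidean silhouette over the first `k` score dimensions;
#' near 0 means the groups are not separated, values near 1 mean tight,
#' well-separated clusters.
#'
#' @param pb a [pca_biplot()] result (or a score matrix).
#' @param labels group labels (defaults to the stored genotype).
#' @param k number of leading components used (default 1).
#' @return mean silhouette width.
#' @export
silhouette_width <- function(pb, labels = NULL, k = 1) {
  s <- if (inherits(pb, "pca_biplot")) pb$scores else as.matrix(pb)
  if (is.null(labels)) labels <- pb$genotype
  s <- s[, seq_len(min(k, ncol(s))), drop = FALSE]
  d <- as.matrix(stats::dist(s))
  n <- nrow(s)
  sil <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(unique(labels[!own]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

## Newton inversion of the trigamma function (for the prior df of the
## moderated variance estimator).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderated two-group test per feature
#'
#' For each (metabolite, isotopomer) feature, the mutant-minus-control
#' mean difference is tested with a moderated t-statistic: the
#' per-feature pooled variance \eqn{s^2} (d degrees of freedom) is shrunk
#' toward a prior \eqn{s_0^2} with prior degrees of freedom \eqn{d_0},
#' \deqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' and \eqn{t = \Delta / (\tilde{s} \sqrt{1/n_1 + 1/n_2})} is referred to
#' a t distribution on \eqn{d + d_0} degrees of freedom. The prior
#' \eqn{(d_0, s_0^2)} is estimated from the ensemble of per-feature
#' variances by moment matching on log variances (digamma/trigamma
#' moments, with Newton inversion of the trigamma function).
#'
#' @param table isotopomer table: data.frame with a two-level `genotype`
#'   column and numeric feature columns.
#' @param d0 optional override of the prior degrees of freedom: `0`
#'   reduces every statistic to the ordinary pooled two-sample t; `Inf`
#'   replaces every variance by the prior \eqn{s_0^2}.
#' @return data.frame with one row per feature: `feature`, `metabolite`,
#'   `delta`, `s2`, `s2_moderated`, `t`, `df`, `p_value`; the estimated
#'   prior is in attributes `d0` and `s02`. Features with zero pooled
#'   variance are flagged `NA` when no moderation is available.
#' @export
moderated_group_test <- function(table, d0 = NULL) {
  fm <- flux_feature_matrix(table)
  x <- fm$x
  g <- fm$genotype
  lev <- sort(unique(g))
  if (length(lev) != 2) stop("genotype must have exactly two levels")
  i1 <- g == "mutant"; i2 <- g == "control"
  if (!any(i1) || !any(i2)) { i1 <- g == lev[2]; i2 <- g == lev[1] }
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stop("need >= 2 samples per genotype")
  d <- n1 + n2 - 2
  delta <- colMeans(x[i1, , drop = FALSE]) - colMeans(x[i2, , drop = FALSE])
  s2 <- ((n1 - 1) * apply(x[i1, , drop = FALSE], 2, stats::var) +
           (n2 - 1) * apply(x[i2, , drop = FALSE], 2, stats::var)) / d
  # prior estimated from the log-variance ensemble
  pos <- s2 > 0
  est <- list(d0 = 0, s02 = NA_real_)
  if (sum(pos) >= 2) {
    z <- log(s2[pos])
    e <- z - digamma(d / 2) + log(d / 2)
    ev <- stats::var(e) - trigamma(d / 2)
    if (is.finite(ev) && ev > 0) {
      est$d0 <- 2 * trigamma_inverse(ev)
      est$s02 <- exp(mean(e) + digamma(est$d0 / 2) - log(est$d0 / 2))
    } else {
      est$d0 <- Inf
      est$s02 <- exp(mean(e))
    }
  }
  if (!is.null(d0)) {
    est$d0 <- d0
    if (is.na(est$s02)) est$s02 <- mean(s2[pos])
  }
  s2_mod <- if (is.infinite(est$d0)) rep(est$s02, length(s2))
  else if (est$d0 == 0) s2
  else (est$d0 * est$s02 + d * s2) / (est$d0 + d)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  t <- delta / se
  df_total <- d + est$d0
  p <- 2 * stats::pt(-abs(t), df_total)
  undefined <- s2 == 0 & est$d0 == 0
  t[undefined] <- NA_real_; p[undefined] <- NA_real_
  out <- data.frame(feature = colnames(x),
                    metabolite = feature_metabolite(colnames(x)),
                    delta = delta, s2 = s2, s2_moderated = s2_mod,
                    t = t, df = df_total, p_value = p)
  rownames(out) <- NULL
  attr(out, "d0") <- est$d0
  attr(out, "s02") <- est$s02
  out
}
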