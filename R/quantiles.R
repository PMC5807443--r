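## Quantile curves and the per-centile difference framework: for each
## centile, the mutant quantile minus the matched control quantile,
## computed per experiment and tested across experiments with a paired
## (one-sample-on-deltas) t-test. This localizes where two distributions
## differ rather than summarizing them by a single location statistic.

#' Linear-interpolation empirical quantile
#'
#' The quantile at position `1 + (n - 1) p` on the sorted sample (the
#' common linear-interpolation convention; `stats::quantile` type 7).
#' Centile deltas depend on this choice, so it is fixed package-wide.
#'
#' @param values nonempty numeric sample.
#' @param p probability (or vector of probabilities) in (0, 1).
#' @return quantile value(s).
#' @examples
#' empirical_quantile(c(10, 20, 30, 40), 0.25)  # 17.5
#' @export
empirical_quantile <- function(values, p) {
  if (length(values) == 0) stop("sample is empty")
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (any(!is.finite(values))) stop("sample contains non-finite values")
  stats::quantile(values, p, type = 7, names = FALSE)
}

#' Empirical quantile curve
#'
#' @param values numeric sample.
#' @param probs strictly increasing probability grid in (0, 1).
#' @param group optional group label attached to every row.
#' @return data.frame of class `"quantile_curve"` with `probs`, `values`
#'   (nondecreasing), `n`, `group`.
#' @export
quantile_curve <- function(values, probs = seq(0.01, 0.99, by = 0.01),
                           group = NA_character_) {
  if (any(diff(probs) <= 0)) stop("probs must be strictly increasing")
  out <- data.frame(probs = probs,
                    values = empirical_quantile(values, probs),
                    n = length(values), group = group)
  class(out) <- c("quantile_curve", "data.frame")
  out
}

## One-sample t on per-experiment deltas (== paired t). Degenerate cases
## follow the framework's contract: all-zero deltas are "no difference"
## (t = 0, p = 1); nonzero constant deltas are infinitely significant.
delta_t_test <- function(d) {
  n <- length(d)
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    if (m == 0) return(list(t = 0, df = n - 1, p = 1))
    return(list(t = sign(m) * Inf, df = n - 1, p = 0))
  }
  t <- m / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}

#' Per-centile quantile differences between paired samples
#'
#' For each experiment and centile, delta = mutant quantile - control
#' quantile (a value above 0 means the mutant distribution is higher at
#' that quantile). Across experiments, each centile gets a two-sided
#' paired t-test; a loess fit (span 0.5) of all per-experiment deltas on
#' centile summarizes the curve. No multiple-testing correction is
#' applied across centiles: the per-centile p-values are reported raw
#' against a 0.05 reference.
#'
#' @param mutant_samples,control_samples lists of numeric vectors, one
#'   per experiment, paired by position (and by name when named).
#' @param centiles integer centile grid (default 1..99).
#' @return object of class `"centile_difference"`: `centiles`,
#'   `per_experiment_delta` (experiment x centile matrix), `mean_delta`,
#'   `t_stat`, `p_value`, `smooth_fit`, `n_experiments`,
#'   `tests_available`.
#' @export
centile_difference <- function(mutant_samples, control_samples,
                               centiles = 1:99) {
  if (!is.list(mutant_samples)) mutant_samples <- list(mutant_samples)
  if (!is.list(control_samples)) control_samples <- list(control_samples)
  if (length(mutant_samples) != length(control_samples)) {
    stop("mutant and control experiment lists must be paired (equal length)")
  }
  if (!is.null(names(mutant_samples)) && !is.null(names(control_samples)) &&
      !identical(names(mutant_samples), names(control_samples))) {
    stop("experiment ids of mutant and control samples do not match")
  }
  if (any(centiles < 1 | centiles > 99)) stop("centiles must be in 1..99")
  n_exp <- length(mutant_samples)
  probs <- centiles / 100
  delta <- t(vapply(seq_len(n_exp), function(i) {
    empirical_quantile(mutant_samples[[i]], probs) -
      empirical_quantile(control_samples[[i]], probs)
  }, numeric(length(centiles))))
  rownames(delta) <- names(mutant_samples) %||% paste0("exp", seq_len(n_exp))
  colnames(delta) <- centiles
  tests_available <- n_exp >= 2
  if (tests_available) {
    tt <- apply(delta, 2, delta_t_test)
    t_stat <- vapply(tt, `[[`, numeric(1), "t")
    p_value <- vapply(tt, `[[`, numeric(1), "p")
  } else {
    t_stat <- rep(NA_real_, length(centiles))
    p_value <- rep(NA_real_, length(centiles))
  }
  long <- data.frame(centile = rep(centiles, each = n_exp),
                     delta = as.vector(delta))
  smooth_fit <- if (length(centiles) >= 10) {
    fit <- stats::loess(delta ~ centile, data = long, span = 0.5,
                        degree = 2)
    stats::predict(fit, newdata = data.frame(centile = centiles))
  } else {
    colMeans(delta)
  }
  structure(list(centiles = centiles,
                 per_experiment_delta = delta,
                 mean_delta = colMeans(delta),
                 t_stat = t_stat, p_value = p_value,
                 smooth_fit = smooth_fit,
                 n_experiments = n_exp,
                 tests_available = tests_available),
            class = "centile_difference")
}

#' @export
print.centile_difference <- function(x, ...) {
  cat("Centile-difference result:", x$n_experiments, "paired experiments,",
      length(x$centiles), "centiles\n")
  if (x$tests_available) {
    sig <- x$centiles[!is.na(x$p_value) & x$p_value < 0.05]
    cat("  centiles with p < 0.05:",
        if (length(sig)) paste(range(sig), collapse = "-") else "none", "\n")
  } else {
    cat("  single experiment: per-centile tests unavailable\n")
  }
  invisible(x)
}

#' Paired t-test on a tail quantile across experiments
#'
#' The p-quantile (default 5th or 95th centile) of each sample is
#' computed per experiment and the mutant-minus-control deltas are
#' tested with a two-sided paired t-test.
#'
#' @inheritParams centile_difference
#' @param p tail probability in (0, 1), typically 0.05 or 0.95.
#' @return list with `statistic` (t), `df`, `p_value`, `mean_delta`,
#'   `deltas`, `prob`.
#' @export
tail_quantile_test <- function(mutant_samples, control_samples, p = 0.95) {
  if (!is.list(mutant_samples)) mutant_samples <- list(mutant_samples)
  if (!is.list(control_samples)) control_samples <- list(control_samples)
  if (length(mutant_samples) != length(control_samples)) {
    stop("mutant and control experiment lists must be paired")
  }
  if (length(mutant_samples) < 2) {
    stop("tail quantile test needs >= 2 paired experiments")
  }
  d <- vapply(seq_along(mutant_samples), function(i) {
    empirical_quantile(mutant_samples[[i]], p) -
      empirical_quantile(control_samples[[i]], p)
  }, numeric(1))
  tt <- delta_t_test(d)
  list(statistic = tt$t, df = tt$df, p_value = tt$p,
       mean_delta = mean(d), deltas = d, prob = p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
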