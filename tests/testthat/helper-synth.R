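# Shared fixtures, all generated in code.

# Random connected mask: a correlated random walk dilated by a 3x3
# structuring element, clipped to a lim x lim window; the largest
# 8-connected component is kept and masks below min_area are rejected.
# This family spans compact blobs to elongated curvilinear shapes, the
# morphologies the segmentation pipeline produces.
rand_walk_mask <- function(seed, lim = 12, len_range = c(2, 10),
                           min_area = 10) {
  for (try in 0:50) {
    set.seed(seed + 100000L * try)
    len <- sample(seq(len_range[1], len_range[2]), 1)
    ang <- cumsum(c(runif(1, 0, 2 * pi), rnorm(max(0, len - 1), 0, 0.6)))
    ctr <- ceiling(lim / 2)
    ys <- round(ctr + cumsum(sin(ang)))
    xs <- round(ctr + cumsum(cos(ang)))
    off <- as.matrix(expand.grid(-1:1, -1:1))
    px <- unique(cbind(rep(ys, each = 9) + off[, 1],
                       rep(xs, each = 9) + off[, 2]))
    px <- px[px[, 1] >= 1 & px[, 1] <= lim &
               px[, 2] >= 1 & px[, 2] <= lim, , drop = FALSE]
    if (nrow(px) < min_area) next
    m <- matrix(FALSE, lim, lim)
    m[px] <- TRUE
    lab <- label_components8(m)
    areas <- tabulate(lab[lab > 0])
    keep <- which.max(areas)
    if (areas[keep] < min_area) next
    return(lab == keep)
  }
  stop("mask generation failed for seed ", seed)
}

# Larger masks (>= 200 px) for the convergence check.
big_walk_mask <- function(seed) {
  rand_walk_mask(seed, lim = 40, len_range = c(50, 80), min_area = 200)
}

# Independent brute-force one-way ANOVA oracle (explicit sums of squares).
anova_oracle <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  lev <- unique(groups)
  ssb <- sum(vapply(lev, function(g) {
    n <- sum(groups == g)
    n * (mean(values[groups == g]) - grand)^2
  }, numeric(1)))
  ssw <- sum(vapply(lev, function(g) {
    sum((values[groups == g] - mean(values[groups == g]))^2)
  }, numeric(1)))
  df1 <- length(lev) - 1
  df2 <- length(values) - length(lev)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2,
                                                  lower.tail = FALSE))
}

# Exhaustive-permutation rank-sum oracle: enumerate all assignments of
# the pooled sample into groups of the observed sizes and compare the
# Mann-Whitney U of the observed split against the permutation law.
ranksum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combs <- utils::combn(n, length(x))
  us <- apply(combs, 2, function(idx) {
    sum(r[idx]) - length(x) * (length(x) + 1) / 2
  })
  mu <- length(x) * length(y) / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  list(W = u_obs, p = p, n_perm = ncol(combs))
}

# Paired object-feature table for fragmentation/rescue statistics,
# drawn from the object-population generator.
make_paired_features <- function(n_experiments, frag_control, frag_mutant,
                                 n_objects, seed, config = synth_config()) {
  rows <- lapply(seq_len(n_experiments), function(e) {
    rbind(
      cbind(gen_object_population(config, frag_control, n_objects,
                                  seed = split_seed(seed, 2L * e - 1L)),
            experiment_id = paste0("exp", e), condition = "control"),
      cbind(gen_object_population(config, frag_mutant, n_objects,
                                  seed = split_seed(seed, 2L * e)),
            experiment_id = paste0("exp", e), condition = "mutant"))
  })
  do.call(rbind, rows)
}
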