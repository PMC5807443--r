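# PCA bi-plot and the moderated group test.

test_that("PCA satisfies its algebraic contracts", {
  set.seed(4)
  x <- matrix(rnorm(8 * 12), 8, 12)
  colnames(x) <- paste0("met", rep(1:4, each = 3), "_M", rep(0:2, 4))
  pb <- pca_biplot(x)
  # reconstruction: scores %*% t(loadings) recovers the centered matrix
  rec <- pb$scores %*% t(pb$loadings)
  expect_equal(rec, scale(x, center = TRUE, scale = FALSE),
               tolerance = 1e-10, ignore_attr = TRUE)
  # loadings orthonormal
  expect_equal(crossprod(pb$loadings), diag(ncol(pb$loadings)),
               tolerance = 1e-10, ignore_attr = TRUE)
  # variance explained nonincreasing, sums to 1
  expect_true(all(diff(pb$variance_explained) <= 1e-12))
  expect_equal(sum(pb$variance_explained), 1)
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(ncol(pb$loadings))) {
    l <- pb$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("rank-1 data and duplicated samples behave as contracted", {
  v <- rnorm(10)
  x <- outer(c(1, 2, 3, 4), v)
  colnames(x) <- paste0("m", 1:10, "_M0")
  pb <- pca_biplot(x)
  expect_equal(pb$variance_explained[1], 1)
  set.seed(5)
  y <- matrix(rnorm(4 * 6), 4, 6)
  y <- rbind(y, y[2, ])
  colnames(y) <- paste0("m", 1:6, "_M0")
  pby <- pca_biplot(y)
  expect_equal(pby$scores[2, ], pby$scores[5, ], ignore_attr = TRUE)
  # zero-variance feature dropped with warning when scaling
  z <- cbind(y, const_M0 = 1)
  expect_warning(pca_biplot(z, scale = TRUE), "zero-variance")
  expect_error(pca_biplot(y[1:2, ]), "samples")
})

test_that("planted metabolites drive the bi-plot at the documented effect", {
  cfg <- synth_config()   # effect_size at the documented threshold
  tab <- gen_isotopomer_table(cfg, seed = 13)
  pb <- pca_biplot(tab)
  expect_gt(silhouette_width(pb), 0.5)
  top5 <- loading_ranks(pb)$metabolite[1:5]
  expect_true(all(cfg$planted_metabolites %in% top5))
})

test_that("silhouette helper agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(6)
  s <- matrix(c(rnorm(6, 0), rnorm(6, 4)), ncol = 1)
  lab <- rep(c("a", "b"), each = 6)
  own <- silhouette_width(s, labels = lab)
  ref <- mean(cluster::silhouette(as.integer(factor(lab)),
                                  dist(s))[, "sil_width"])
  expect_equal(own, ref, tolerance = 1e-12)
})

test_that("moderated test reduces to ordinary t at d0 = 0 and to the prior at d0 = Inf", {
  tab <- gen_isotopomer_table(synth_config(effect_size = 1), seed = 23)
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  mt0 <- moderated_group_test(tab, d0 = 0)
  # ordinary pooled two-sample t, feature by feature
  for (f in num[c(1, 5, 9, 20)]) {
    ht <- t.test(tab[[f]][tab$genotype == "mutant"],
                 tab[[f]][tab$genotype == "control"], var.equal = TRUE)
    expect_equal(mt0$t[mt0$feature == f], unname(ht$statistic),
                 tolerance = 1e-10)
    expect_equal(mt0$p_value[mt0$feature == f], ht$p.value,
                 tolerance = 1e-10)
  }
  mtI <- moderated_group_test(tab, d0 = Inf)
  expect_equal(unique(round(mtI$s2_moderated, 15)),
               round(attr(mtI, "s02"), 15))
})

test_that("moderated variance lies between the feature and prior variance", {
  tab <- gen_isotopomer_table(synth_config(), seed = 29)
  mt <- moderated_group_test(tab)
  s02 <- attr(mt, "s02")
  expect_true(all(mt$s2_moderated >= pmin(mt$s2, s02) - 1e-15))
  expect_true(all(mt$s2_moderated <= pmax(mt$s2, s02) + 1e-15))
  expect_gt(attr(mt, "d0"), 0)
})

test_that("moderated statistics agree with the reference implementation", {
  skip_if_not_installed("limma")
  tab <- gen_isotopomer_table(synth_config(effect_size = 1.5), seed = 31)
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  y <- t(as.matrix(tab[, num]))
  design <- cbind(1, as.integer(tab$genotype == "mutant"))
  fit <- limma::eBayes(limma::lmFit(y, design))
  mt <- moderated_group_test(tab)
  expect_equal(attr(mt, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(mt, "s02"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(mt$t, fit$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(mt$p_value, fit$p.value[, 2], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("the null generator keeps the moderated test calibrated", {
  rej <- vapply(1:60, function(s) {
    tab <- gen_isotopomer_table(synth_config(effect_size = 0),
                                seed = split_seed(400, s))
    mean(moderated_group_test(tab)$p_value < 0.05, na.rm = TRUE)
  }, numeric(1))
  # mean rejection near alpha (moderated tests share the variance prior,
  # so per-table rates correlate; the band is the binomial CI inflated
  # for that dependence)
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})
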