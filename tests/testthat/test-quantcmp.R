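# Quantile machinery, centile-difference framework, and the figure-level
# paired statistics.

test_that("empirical quantile follows the 1+(n-1)p interpolation rule", {
  expect_equal(empirical_quantile(c(10, 20, 30, 40), 0.25), 17.5)
  expect_equal(empirical_quantile(rep(7, 50), 0.01), 7)
  expect_equal(empirical_quantile(rep(7, 50), 0.99), 7)
  expect_equal(empirical_quantile(c(0.2, 0.4, 0.6, 0.8), 0.25), 0.35)
  expect_equal(empirical_quantile(c(1, 2, 3, 4), 0.5), 2.5)
  set.seed(1)
  expect_lt(abs(empirical_quantile(rnorm(10000), 0.5)), 0.05)
  expect_error(empirical_quantile(numeric(0), 0.5), "empty")
  expect_error(empirical_quantile(1:10, 0), "p must")
})

test_that("quantile curves are monotone with strictly increasing probs", {
  set.seed(2)
  for (i in 1:20) {
    qc <- quantile_curve(rlnorm(50 + i))
    expect_true(all(diff(qc$values) >= 0))
    expect_true(all(diff(qc$probs) > 0))
  }
  expect_error(quantile_curve(1:10, probs = c(0.5, 0.5)), "increasing")
})

test_that("centile differences satisfy the framework contracts", {
  set.seed(3)
  xs <- lapply(1:5, function(i) rnorm(300))
  # identical samples: all deltas 0, all p = 1
  cd0 <- centile_difference(xs, xs)
  expect_true(all(cd0$per_experiment_delta == 0))
  expect_true(all(cd0$t_stat == 0))
  expect_true(all(cd0$p_value == 1))
  # pure location shift: quantiles are equivariant
  cd5 <- centile_difference(lapply(xs, `+`, 5), xs)
  expect_equal(unname(cd5$mean_delta), rep(5, 99), tolerance = 1e-12)
  expect_true(all(cd5$p_value >= 0 & cd5$p_value <= 1))
  # unpaired inputs rejected
  expect_error(centile_difference(xs[1:3], xs[1:2]), "paired")
  # single experiment: deltas come back, tests flagged unavailable
  cd1 <- centile_difference(xs[1], lapply(xs, `+`, 1)[1])
  expect_false(cd1$tests_available)
  expect_true(all(is.na(cd1$p_value)))
  expect_equal(nrow(cd1$per_experiment_delta), 1)
})

test_that("planted upper-tail shifts localize to upper centiles", {
  cfg <- synth_config(n_events = 4000, tail_shift_delta = 0.15,
                      tail_fraction = 0.3)
  exps <- gen_flow_experiments(cfg, n_experiments = 6, seed = 99)
  mt <- lapply(exps, function(e) log10(e$mutant$tmrm_raw))
  ct <- lapply(exps, function(e) log10(e$control$tmrm_raw))
  cd <- centile_difference(mt, ct)
  upper <- cd$centiles >= 80 & cd$centiles <= 95
  lower <- cd$centiles <= 60
  expect_true(all(cd$p_value[upper] < 0.05))
  expect_true(all(cd$mean_delta[upper] > 0))
  expect_lt(mean(cd$p_value[lower] < 0.05), 0.25)
  expect_lt(max(abs(cd$mean_delta[cd$centiles <= 50])), 0.05)
})

test_that("tail quantile test matches the closed-form paired t", {
  # deltas (1, 0, 1): t = mean/(sd/sqrt(3)) = 2, df = 2, p = 0.1835
  mut <- list(c(1, 2, 3) + 1, c(4, 5, 6), c(7, 8, 9) + 1)
  ctl <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  r <- tail_quantile_test(mut, ctl, 0.95)
  expect_equal(r$deltas, c(1, 0, 1))
  expect_equal(r$statistic, 2, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, 2 * pt(-2, 2), tolerance = 1e-12)
  expect_equal(r$p_value, 0.1835, tolerance = 1e-3)
  # identical groups: t = 0, p = 1
  r0 <- tail_quantile_test(ctl, ctl, 0.05)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(tail_quantile_test(mut[1], ctl[1], 0.95), "experiments")
})

test_that("fragmentation statistic pairs experiments and detects the gap", {
  feats <- make_paired_features(5, 0.3, 0.8, n_objects = 120, seed = 55)
  fs <- fragmentation_stat(feats)
  expect_equal(nrow(fs$per_experiment), 5)
  expect_true(all(fs$per_experiment$delta > 0))
  expect_lt(fs$p_value, 0.01)
  # identical arms give p = 1
  same <- feats[feats$condition == "control", ]
  both <- rbind(same, transform(same, condition = "mutant"))
  expect_equal(fragmentation_stat(both)$p_value, 1)
  # missing pair is named
  expect_error(fragmentation_stat(feats[feats$condition == "control", ]),
               "exp1")
})

test_that("rescue deltas follow the sign convention and pair plasmids", {
  cfg <- synth_config()
  rows <- list()
  for (e in 1:4) {
    for (pl in c("CTT", "MTS-control")) {
      frag_tr <- if (pl == "CTT") 0.4 else 0.8
      rows[[length(rows) + 1]] <- rbind(
        cbind(gen_object_population(cfg, frag_tr, 100,
                                    seed = split_seed(800 + e, 1)),
              experiment_id = paste0("exp", e), plasmid = pl,
              transfected = TRUE),
        cbind(gen_object_population(cfg, 0.8, 100,
                                    seed = split_seed(800 + e, 2)),
              experiment_id = paste0("exp", e), plasmid = pl,
              transfected = FALSE))
    }
  }
  feats <- do.call(rbind, rows)
  rd <- rescue_delta(feats)
  ctt <- rd$deltas$delta[rd$deltas$plasmid == "CTT"]
  ctl <- rd$deltas$delta[rd$deltas$plasmid == "MTS-control"]
  expect_true(all(ctt < 0))            # elongation => negative delta
  expect_lt(mean(abs(ctl)), mean(abs(ctt)))
  expect_lt(rd$p_value, 0.05)
  # transfected == untransfected everywhere: all deltas 0
  null_feats <- transform(feats[feats$transfected, ], transfected = FALSE)
  rd0 <- rescue_delta(rbind(feats[feats$transfected, ], null_feats))
  expect_true(all(rd0$deltas$delta == 0))
  # unmatched plasmid arms error
  expect_error(rescue_delta(feats[feats$plasmid == "CTT" |
                                    feats$experiment_id != "exp1", ]),
               "matched|lacks")
})

test_that("median area test computes paired medians and curves", {
  areas <- do.call(rbind, lapply(1:4, function(e) {
    set.seed(600 + e)
    a <- rlnorm(80, 3, 0.5)
    rbind(data.frame(area = a, experiment_id = paste0("exp", e),
                     condition = "control"),
          data.frame(area = 1.5 * a, experiment_id = paste0("exp", e),
                     condition = "mutant"))
  }))
  mt <- median_area_test(areas)
  per <- mt$per_experiment
  d <- per$median_area[per$condition == "mutant"] -
    per$median_area[per$condition == "control"]
  expect_true(all(d > 0))
  expect_lt(mt$p_value, 0.05)
  expect_true(all(tapply(mt$curves$values, mt$curves$group,
                         function(v) all(diff(v) >= 0))))
  # identical lists: p = 1
  same <- areas[areas$condition == "control", ]
  mt0 <- median_area_test(rbind(same, transform(same, condition = "mutant")))
  expect_equal(mt0$p_value, 1)
  expect_error(median_area_test(areas[areas$condition == "control", ]),
               "mutant")
})

test_that("proportion ANOVA matches the brute-force oracle", {
  counts <- data.frame(
    genotype = rep(c("control", "mutant"), each = 3),
    aberrant = c(10, 20, 15, 60, 70, 65),
    normal = c(90, 80, 85, 40, 30, 35))
  av <- proportion_anova(counts)
  oracle <- anova_oracle(counts$aberrant / 100, counts$genotype)
  expect_equal(av$F, oracle$F, tolerance = 1e-10)
  expect_equal(av$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(av$df1, oracle$df1)
  expect_equal(av$df2, oracle$df2)
  # constant proportions: F = 0, p = 1 by contract
  const <- data.frame(genotype = rep(c("a", "b"), each = 2),
                      aberrant = c(1, 2, 3, 4), normal = c(9, 18, 27, 36))
  av0 <- proportion_anova(const)
  expect_equal(av0$F, 0)
  expect_equal(av0$p_value, 1)
  # zero-total fields are excluded with a warning
  zt <- rbind(counts, data.frame(genotype = "control", aberrant = 0,
                                 normal = 0))
  expect_warning(proportion_anova(zt), "zero-total")
})

test_that("planted aberrant-proportion gaps are strongly detected", {
  cfg <- synth_config(n_fields = 30,
                      p_aberrant_by_genotype = c(control = 0.1, mutant = 0.6))
  av <- proportion_anova(gen_field_counts(cfg, seed = 77))
  expect_lt(av$p_value, 0.001)
})

test_that("group tests agree with exhaustive and closed-form oracles", {
  # rank-sum on {1,2,3} vs {4,5,6}: all 20 assignments enumerated
  d <- data.frame(value = c(1, 2, 3, 4, 5, 6),
                  group = rep(c("a", "b"), each = 3))
  gt <- group_tests(d, "rank_sum")
  oracle <- ranksum_oracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(oracle$n_perm, 20)
  expect_equal(gt$statistic, oracle$W)
  expect_equal(gt$p_value, oracle$p, tolerance = 1e-12)
  # a second configuration against the enumeration oracle
  d2 <- data.frame(value = c(1, 5, 2, 4, 3, 7, 8),
                   group = c("a", "a", "a", "b", "b", "b", "b"))
  gt2 <- group_tests(d2, "rank_sum")
  o2 <- ranksum_oracle(c(1, 5, 2), c(4, 3, 7, 8))
  expect_equal(gt2$p_value, o2$p, tolerance = 1e-12)
  # paired t on deltas (1, 0, 1)
  pd <- data.frame(value = c(2, 4, 7, 1, 4, 6), pair_id = rep(1:3, 2),
                   group = rep(c("x", "y"), each = 3))
  pt_ <- group_tests(pd, "paired_t")
  expect_equal(pt_$statistic, 2, tolerance = 1e-12)
  expect_equal(pt_$p_value, 2 * pt(-2, 2), tolerance = 1e-12)
  # identical groups
  idf <- data.frame(value = rep(c(0.3, 0.4, 0.5), 2),
                    group = rep(c("a", "b"), each = 3))
  expect_equal(group_tests(idf, "fraction_t")$p_value, 1)
  idf$pair_id <- rep(1:3, 2)
  expect_equal(group_tests(idf, "paired_t")$p_value, 1)
  expect_gte(group_tests(idf, "rank_sum")$p_value, 0.99)
  # pairing violations
  bad <- data.frame(value = 1:4, group = c("a", "a", "b", "b"),
                    pair_id = c(1, 2, 1, 3))
  expect_error(group_tests(bad, "paired_t"), "pairing")
  expect_error(group_tests(data.frame(value = c(0.2, 1.4),
                                      group = c("a", "b")), "fraction_t"),
               "fraction")
})
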