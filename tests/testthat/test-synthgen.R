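# Synthetic-data generators: determinism, planted-truth retrievability,
# and the marginal structure the downstream analyses assume.

test_that("synth_config validates its invariants", {
  expect_s3_class(synth_config(), "synth_config")
  expect_error(synth_config(fragmentation = 1.2), "fragmentation")
  expect_error(synth_config(tail_fraction = 0), "tail_fraction")
  expect_error(synth_config(n_events = 0), "counts")
  expect_error(synth_config(fragment_radius_px = -1), "scale")
  expect_error(synth_config(effect_size = -0.5), "effect_size")
  expect_error(synth_config(p_aberrant_by_genotype = c(control = -0.1,
                                                       mutant = 0.5)),
               "probabilities")
})

test_that("every generator is a pure function of (config, seed)", {
  cfg <- synth_config(image_shape = c(96L, 96L), n_objects_per_field = 5,
                      n_events = 200, droplet_density = 5, n_fields = 4)
  expect_identical(gen_mito_field(cfg, 0.5, seed = 9),
                   gen_mito_field(cfg, 0.5, seed = 9))
  expect_identical(gen_droplet_field(cfg, 1.2, seed = 9),
                   gen_droplet_field(cfg, 1.2, seed = 9))
  expect_identical(gen_flow_sample(cfg, "mutant", seed = 9),
                   gen_flow_sample(cfg, "mutant", seed = 9))
  expect_identical(gen_isotopomer_table(cfg, seed = 9),
                   gen_isotopomer_table(cfg, seed = 9))
  expect_identical(gen_field_counts(cfg, seed = 9),
                   gen_field_counts(cfg, seed = 9))
})

test_that("mito fields carry retrievable truth and honor fragmentation", {
  cfg <- synth_config(image_shape = c(160L, 160L), n_objects_per_field = 8)
  f <- gen_mito_field(cfg, 1, seed = 3)
  expect_equal(nrow(f$truth), 8)
  expect_true(all(f$truth$class == "fragment"))
  expect_equal(max(f$labels), 8)
  expect_true(all(f$image >= 0) && all(is.finite(f$image)))
  # discs of one radius all share the same rasterized solidity, higher
  # than any tubule's (frozen from the package's own oracle: a radius-3
  # digital disc is 29 px with hull 37)
  feats <- compute_features(f$labels)
  expect_equal(unique(feats$solidity), 29 / 37)

  f0 <- gen_mito_field(cfg, 0, seed = 3)
  expect_true(all(f0$truth$class == "tubule"))
  s0 <- compute_features(f0$labels)$solidity
  expect_lt(median(s0), median(feats$solidity))

  expect_error(gen_mito_field(cfg, 1.5), "fragmentation")
})

test_that("radius-4 fragment fields score the frozen disc solidity", {
  cfg <- synth_config(image_shape = c(160L, 160L), n_objects_per_field = 6,
                      fragment_radius_px = 4, background_sigma = 0,
                      photon_scale = Inf)
  f <- gen_mito_field(cfg, 1, seed = 5)
  feats <- compute_features(f$labels, oracle = TRUE)
  # 49-px digital disc, rasterized hull 57: solidity 49/57 for every disc
  expect_equal(unique(feats$solidity), 49 / 57)
  expect_gte(min(feats$solidity), 0.85)
})

test_that("object placement failure reports the attempted density", {
  cfg <- synth_config(image_shape = c(48L, 48L), n_objects_per_field = 60)
  expect_error(gen_mito_field(cfg, 1, seed = 1), "density")
})

test_that("droplet fields scale areas and handle the empty case", {
  cfg <- synth_config(image_shape = c(200L, 200L), droplet_density = 10)
  empty <- gen_droplet_field(synth_config(droplet_density = 0), 1, seed = 2)
  expect_length(empty$truth_areas, 0)
  expect_equal(max(empty$labels), 0)

  bigger <- vapply(1:10, function(k) {
    a1 <- gen_droplet_field(cfg, 1, seed = split_seed(70, k))$truth_areas
    a2 <- gen_droplet_field(cfg, 1.5, seed = split_seed(71, k))$truth_areas
    median(a2) > median(a1)
  }, logical(1))
  expect_gte(sum(bigger), 9)

  expect_error(gen_droplet_field(cfg, -1), "area_scale")
})

test_that("flow samples carry the planted scatter and tail structure", {
  cfg <- synth_config(n_events = 50000, fsc_beta = 0, ssc_beta = 0,
                      tail_shift_delta = 0)
  s <- gen_flow_sample(cfg, "control", seed = 11)
  expect_equal(nrow(s), 50000)
  expect_lt(abs(cor(log10(s$tmrm_raw), log10(s$fsc))), 0.02)
  expect_lt(abs(cor(log10(s$tmrm_raw), log10(s$ssc))), 0.02)
  # null configuration: mutant and control come from the same law
  m <- gen_flow_sample(cfg, "mutant", seed = 11)
  expect_equal(m$tmrm_raw, s$tmrm_raw)
  expect_equal(attr(m, "truth")$tail_shift_delta, 0)

  expect_error(gen_flow_sample(synth_config(n_events = 50)), "n_events")
  expect_error(gen_flow_sample(synth_config(tail_fraction = 1.5)),
               "tail_fraction")
})

test_that("isotopomer tables are Dirichlet-normalized with default design", {
  tab <- gen_isotopomer_table(synth_config(), seed = 21)
  expect_equal(table(tab$genotype), table(rep(c("control", "mutant"), 3)),
               ignore_attr = TRUE)   # three replicates per genotype
  num <- names(tab)[vapply(tab, is.numeric, logical(1))]
  for (m in unique(feature_metabolite(num))) {
    cols <- num[feature_metabolite(num) == m]
    expect_equal(rowSums(tab[, cols]), rep(1, nrow(tab)),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  expect_true(all(as.matrix(tab[, num]) >= 0 & as.matrix(tab[, num]) <= 1))
  expect_error(gen_isotopomer_table(
    synth_config(planted_metabolites = "nonexistent")), "subset")
})

test_that("field counts concentrate around the planted proportions", {
  cfg <- synth_config(n_fields = 30,
                      p_aberrant_by_genotype = c(control = 0.1, mutant = 0.6))
  fc <- gen_field_counts(cfg, seed = 31)
  expect_equal(nrow(fc), 60)
  prop <- tapply(fc$aberrant / (fc$normal + fc$aberrant), fc$genotype, mean)
  expect_lt(abs((prop[["mutant"]] - prop[["control"]]) - 0.5), 0.1)
  # identical probabilities plant a null table
  null_cfg <- synth_config(p_aberrant_by_genotype = c(control = 0.3,
                                                      mutant = 0.3))
  expect_equal(attr(gen_field_counts(null_cfg, seed = 1), "truth")$p_aberrant,
               c(control = 0.3, mutant = 0.3))
  expect_error(gen_field_counts(synth_config(n_fields = 1)), "fields")
})
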