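# mitomorph

Quantification of mitochondrial network morphology, membrane potential
and metabolic phenotypes in paired mutant/control cell-line
experiments.

Loss of polycystin-1 in renal epithelial cells is accompanied by a
cluster of mitochondrial phenotypes: the mitochondrial network
fragments, the TMRM membrane-potential distribution shifts in its
upper centiles, lipid droplets enlarge after fatty-acid loading,
metabolic flux routing of ¹³C-labelled glucose changes, and more
mitochondria look ultrastructurally aberrant. `mitomorph` implements
the statistical machinery used to quantify each of those readouts, for
analysts who have paired imaging / cytometry / metabolomics readouts
per experiment and want distribution-level, paired inference rather
than single-summary comparisons.

## What it computes

* **Solidity index** — per segmented object, area divided by
  rasterized convex-hull area. Fragmented, disconnected mitochondria
  score high; connected curvilinear networks score low. Per
  experiment the 25th centile of object solidity is the fragmentation
  statistic, compared mutant vs control with a paired t-test:
  for experiments *e* = 1..n, Δₑ = Q₀.₂₅(solidity, mutant) −
  Q₀.₂₅(solidity, control), with t = mean(Δ)/(sd(Δ)/√n). An exact
  polygon-geometry oracle (`convention = "polygon"`) backs the
  rasterized fast path in the tests.
* **Centile-difference curves** — for each centile c = 1..99,
  Δₑ(c) = Q꜀(mutant) − Q꜀(control) per experiment, a per-centile
  paired t-test across experiments, a loess summary fit, and paired
  tail tests at the 5th/95th centiles. Quantiles use the 1+(n−1)p
  linear-interpolation rule throughout.
* **TMRM scatter correction** — within each sample, least squares of
  log₁₀(TMRM) on log₁₀(FSC) and log₁₀(SSC); corrected intensity is
  10^(residual + grand mean), removing cell-size/granularity
  dependence while preserving the geometric mean.
* **Lipid droplet areas** — segmentation, per-experiment median areas,
  paired t across experiments, quantile curves for plotting.
* **Aberrant-mitochondria proportions** — per-field proportions,
  one-way ANOVA on genotype within cell source.
* **Isotopomer fluxomics** — PCA bi-plot of mass-isotopomer
  fractional abundances (SVD, deterministic sign convention) and an
  empirical-Bayes moderated t per (metabolite, isotopomer) feature:
  s̃² = (d₀s₀² + ds²)/(d₀ + d) with (d₀, s₀²) moment-matched on log
  variances.
* **Synthetic data with planted truth** — generators for micrograph
  fields (random-walk tubules vs disc fragments), 50,000-event flow
  samples with planted scatter coefficients and upper-tail shifts,
  lognormal droplet fields, Dirichlet isotopomer tables and EM field
  counts, all pure functions of `(config, seed)`.

## Worked example

Five paired experiments, ten fields each, segmented and scored end to
end (control fields drawn mostly tubular, mutant fields mostly
fragmented):

```r
library(mitomorph)
cfg <- synth_config(image_shape = c(256L, 256L), n_objects_per_field = 16)
feats <- list()
for (e in 1:5) {
  for (cond in c("control", "mutant")) {
    frag <- if (cond == "control") 0.3 else 0.8
    fields <- gen_mito_experiment(cfg, frag, n_fields = 10,
                                  seed = split_seed(100 + e, cond == "mutant"))
    for (k in seq_along(fields)) {
      lab <- segment_objects(fields[[k]])
      feats[[length(feats) + 1]] <- compute_features(
        lab, field_id = k, experiment_id = paste0("exp", e), condition = cond)
    }
  }
}
feats <- do.call(rbind, feats)
fs <- fragmentation_stat(feats)
fs$per_experiment
#>   experiment_id   control    mutant     delta
#> 1          exp1 0.5591599 0.7837838 0.2246239
#> 2          exp2 0.5455774 0.7837838 0.2382064
#> 3          exp3 0.5495050 0.7837838 0.2342788
#> 4          exp4 0.5477387 0.7837838 0.2360451
#> 5          exp5 0.5490966 0.7837838 0.2346872
sprintf("paired t = %.2f on %d df, p = %.2g", fs$statistic, fs$df, fs$p_value)
#> [1] "paired t = 99.86 on 4 df, p = 6e-08"
```

Reading the output: each row is one experiment's 25th-centile object
solidity per arm. Control networks (mostly curvilinear tubules) sit
near 0.55; mutant populations are dominated by compact fragments, so
their 25th centile lands on the fragment solidity plateau (synthetic
fragments are discs of one radius, hence one solidity, 29/37 ≈ 0.784).
Every delta is positive — more fragmented mutant networks — and the
paired t-test across the five experiments is decisive.

The same pattern runs for the other assays: `tmrm_pipeline()` for
corrected membrane-potential centile curves, `median_area_test()` for
droplets, `proportion_anova()` for EM counts, `pca_biplot()` +
`moderated_group_test()` for fluxomics, and `run_pipeline()` to drive
everything from a YAML manifest (a demo manifest ships in
`inst/extdata/`). `exec/mitomorph` exposes the same operations as a
command line.

## Vignette

`vignettes/mitomorph-methods.Rmd` documents the model and its
assumptions: the two convex-hull conventions and why the corner-point
raster convention was adopted, the quantile convention, the per-sample
correction design, what the synthetic generators emulate and what they
deliberately do not, the documented flux effect-size threshold, and
the handling of degenerate inputs.
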