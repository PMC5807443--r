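## Configuration for the synthetic-data generators. Defaults reproduce the
## study conditions the analyses assume: ~16 objects per field so that 50
## fields give ~800 mitochondria per experiment, 50,000 cytometry events
## per sample, 3 replicates per genotype for fluxomics, and >= 29
## electron-microscopy fields per condition.

#' Synthetic-data generator configuration
#'
#' Bundles every tunable of the generators with validated defaults. All
#' generators are pure functions of `(config, seed)`: identical inputs
#' give bit-identical outputs.
#'
#' @param image_shape image height and width in pixels.
#' @param n_objects_per_field mitochondrial objects drawn per field.
#' @param fragmentation fraction in \[0,1\] of objects drawn as compact
#'   round fragments rather than elongated curvilinear tubules.
#' @param tubule_length_px random-walk skeleton length of a tubule.
#' @param tubule_curvature sd of the per-step heading change (radians);
#'   larger values give more tortuous, lower-solidity tubules.
#' @param fragment_radius_px disc radius of a fragment.
#' @param background_sigma Gaussian background noise sd (intensity units).
#' @param photon_scale Poisson shot-noise scale: counts are drawn as
#'   `rpois(intensity * photon_scale) / photon_scale`, so larger values
#'   mean relatively less shot noise; `Inf` disables it.
#' @param droplet_density lipid droplets drawn per field.
#' @param droplet_log_area_mu,droplet_log_area_sigma lognormal parameters
#'   of droplet area (px^2).
#' @param n_events cytometry events per sample (default 50,000 recorded
#'   live single cells).
#' @param fsc_beta,ssc_beta planted log10-linear coefficients of TMRM on
#'   forward/side scatter.
#' @param tail_shift_delta planted additive log10 shift of the mutant
#'   TMRM baseline, applied to the upper tail only.
#' @param tail_fraction fraction in (0,1\] of the baseline distribution
#'   (from the top) carrying the shift.
#' @param n_fields electron-microscopy fields per condition.
#' @param p_aberrant_by_genotype named vector of per-genotype
#'   probabilities that a mitochondrion is scored aberrant.
#' @param n_samples_per_group fluxomics replicates per genotype.
#' @param planted_metabolites metabolites receiving a genotype-dependent
#'   isotopomer shift.
#' @param effect_size magnitude of that shift (log concentration units of
#'   the Dirichlet parameters).
#' @param seed default random seed.
#' @return a validated list of class `"synth_config"`.
#' @export
synth_config <- function(image_shape = c(256L, 256L),
                         n_objects_per_field = 16,
                         fragmentation = 0.5,
                         tubule_length_px = 30,
                         tubule_curvature = 0.35,
                         fragment_radius_px = 3,
                         background_sigma = 8,
                         photon_scale = 1,
                         droplet_density = 40,
                         droplet_log_area_mu = log(30),
                         droplet_log_area_sigma = 0.7,
                         n_events = 50000,
                         fsc_beta = 0.5,
                         ssc_beta = 0.3,
                         tail_shift_delta = 0.15,
                         tail_fraction = 0.3,
                         n_fields = 30,
                         p_aberrant_by_genotype = c(control = 0.1, mutant = 0.6),
                         n_samples_per_group = 3,
                         planted_metabolites = c("citrate", "malate", "glutamate"),
                         effect_size = 2.5,
                         seed = 1L) {
  cfg <- list(
    image_shape = as.integer(image_shape),
    n_objects_per_field = as.integer(n_objects_per_field),
    fragmentation = fragmentation,
    tubule_length_px = tubule_length_px,
    tubule_curvature = tubule_curvature,
    fragment_radius_px = fragment_radius_px,
    background_sigma = background_sigma,
    photon_scale = photon_scale,
    droplet_density = as.integer(droplet_density),
    droplet_log_area_mu = droplet_log_area_mu,
    droplet_log_area_sigma = droplet_log_area_sigma,
    n_events = as.integer(n_events),
    fsc_beta = fsc_beta,
    ssc_beta = ssc_beta,
    tail_shift_delta = tail_shift_delta,
    tail_fraction = tail_fraction,
    n_fields = as.integer(n_fields),
    p_aberrant_by_genotype = p_aberrant_by_genotype,
    n_samples_per_group = as.integer(n_samples_per_group),
    planted_metabolites = planted_metabolites,
    effect_size = effect_size,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$image_shape) == 2, all(cfg$image_shape >= 8))
  if (cfg$fragmentation < 0 || cfg$fragmentation > 1)
    stop("fragmentation must be in [0, 1]")
  if (cfg$tail_fraction <= 0 || cfg$tail_fraction > 1)
    stop("tail_fraction must be in (0, 1]")
  if (any(cfg$p_aberrant_by_genotype < 0 | cfg$p_aberrant_by_genotype > 1))
    stop("aberrant probabilities must be in [0, 1]")
  counts <- c(cfg$n_objects_per_field, cfg$n_events, cfg$n_fields,
              cfg$n_samples_per_group)
  if (any(counts < 1)) stop("all counts must be >= 1")
  scales <- c(cfg$tubule_length_px, cfg$fragment_radius_px,
              cfg$photon_scale, cfg$droplet_log_area_sigma)
  if (any(scales <= 0)) stop("all scale parameters must be > 0")
  if (cfg$background_sigma < 0) stop("background_sigma must be >= 0")
  if (cfg$effect_size < 0) stop("effect_size must be >= 0")
  invisible(cfg)
}

#' Derive a per-item seed from a base seed and an item counter
#'
#' Multi-item generators (fields of an experiment, samples of a run)
#' re-seed each item as `(seed * 48271 + k) mod (2^31 - 1)` so any single
#' item is reproducible in isolation from `(base seed, counter)` alone.
#'
#' @param seed base integer seed.
#' @param k item counter (>= 0).
#' @return derived integer seed.
#' @export
split_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + k) %% 2147483647)
}
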