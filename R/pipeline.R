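## Orchestration: a run manifest names an ordered list of analysis
## stages with parameters and one seed; run_pipeline() executes
## simulate -> segment -> features -> statistics for each stage, logging
## record counts, and writes a provenance file echoing the manifest plus
## content hashes. Re-executing a manifest reproduces identical outputs:
## every stochastic stage is re-seeded from the manifest seed via
## split_seed(), and no timestamps enter the tracked outputs (wall-clock
## lines go to run.log, which is outside the reproducibility contract).

pipeline_stages <- c("mito", "droplets", "tmrm", "flux", "emcounts")

#' Read and validate a run manifest
#'
#' A manifest is a YAML file (or an equivalent list) with fields `seed`
#' (integer), optional `config` ([synth_config()] overrides applied to
#' every stage) and `stages`: a list of `{stage: <name>, params: {...}}`
#' entries with `stage` one of `mito`, `droplets`, `tmrm`, `flux`,
#' `emcounts`.
#'
#' @param manifest path to a YAML manifest or a list.
#' @return validated manifest list.
#' @export
read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest file not found: ", manifest)
    manifest <- yaml::read_yaml(manifest)
  }
  if (is.null(manifest$seed)) stop("manifest schema error: field 'seed' is required")
  if (is.null(manifest$stages) || length(manifest$stages) == 0) {
    stop("manifest schema error: field 'stages' must list at least one stage")
  }
  for (i in seq_along(manifest$stages)) {
    st <- manifest$stages[[i]]
    if (is.null(st$stage)) {
      stop("manifest schema error: stages[", i, "] lacks the 'stage' field")
    }
    if (!st$stage %in% pipeline_stages) {
      stop("manifest schema error: stages[", i, "].stage = '", st$stage,
           "' is not one of: ", paste(pipeline_stages, collapse = ", "))
    }
  }
  manifest
}

stage_config <- function(manifest, params) {
  overrides <- c(params$config, manifest$config)
  overrides <- overrides[!duplicated(names(overrides))]
  do.call(synth_config, overrides[names(overrides) %in%
                                    names(formals(synth_config))])
}

pipeline_log <- function(log_path, ...) {
  cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "|", ..., "\n",
      file = log_path, append = TRUE)
}

run_stage_mito <- function(cfg, params, seed, out_dir, log) {
  n_exp <- params$n_experiments %||% 2
  n_fields <- params$n_fields %||% 4
  fc <- params$fragmentation_control %||% 0.3
  fm <- params$fragmentation_mutant %||% 0.8
  feats <- list()
  for (e in seq_len(n_exp)) {
    for (cond in c("control", "mutant")) {
      frag <- if (cond == "control") fc else fm
      fields <- gen_mito_experiment(cfg, frag, n_fields = n_fields,
                                    seed = split_seed(seed, 100L * e +
                                                        (cond == "mutant")))
      for (k in seq_along(fields)) {
        lab <- segment_objects(fields[[k]])
        feats[[length(feats) + 1L]] <- compute_features(
          lab, fields[[k]]$image, field_id = k,
          experiment_id = paste0("exp", e), condition = cond)
      }
    }
  }
  features <- do.call(rbind, feats)
  write_table_csv(features, file.path(out_dir, "mito_features.csv"))
  fs <- fragmentation_stat(features)
  write_stats_json(list(per_experiment = fs$per_experiment,
                        statistic = fs$statistic, df = fs$df,
                        p_value = fs$p_value, q = fs$q),
                   file.path(out_dir, "mito_fragmentation.json"))
  pipeline_log(log, "mito:", nrow(features), "objects,", n_exp,
               "experiments, paired p =", signif(fs$p_value, 3))
}

run_stage_droplets <- function(cfg, params, seed, out_dir, log) {
  n_exp <- params$n_experiments %||% 4
  scale_mut <- params$area_scale_mutant %||% 1.5
  rows <- list()
  for (e in seq_len(n_exp)) {
    for (cond in c("control", "mutant")) {
      fld <- gen_droplet_field(cfg, if (cond == "mutant") scale_mut else 1,
                               seed = split_seed(seed, 10L * e +
                                                   (cond == "mutant")))
      lab <- segment_droplets(fld)
      f <- compute_features(lab)
      if (nrow(f)) {
        rows[[length(rows) + 1L]] <- data.frame(
          area = f$area_px, experiment_id = paste0("exp", e), condition = cond)
      }
    }
  }
  areas <- do.call(rbind, rows)
  write_table_csv(areas, file.path(out_dir, "droplet_areas.csv"))
  mt <- median_area_test(areas)
  write_table_csv(mt$curves, file.path(out_dir, "droplet_quantiles.csv"))
  write_stats_json(list(per_experiment = mt$per_experiment,
                        statistic = mt$statistic, df = mt$df,
                        p_value = mt$p_value),
                   file.path(out_dir, "droplet_test.json"))
  pipeline_log(log, "droplets:", nrow(areas), "droplets, paired p =",
               signif(mt$p_value, 3))
}

run_stage_tmrm <- function(cfg, params, seed, out_dir, log) {
  n_exp <- params$n_experiments %||% 10
  exps <- gen_flow_experiments(cfg, n_experiments = n_exp, seed = seed)
  res <- tmrm_pipeline(exps)
  cd <- res$centile
  write_table_csv(data.frame(centile = cd$centiles,
                             mean_delta = cd$mean_delta,
                             t = cd$t_stat, p_value = cd$p_value,
                             smooth = cd$smooth_fit),
                  file.path(out_dir, "tmrm_centile.csv"))
  tails <- lapply(res$tails, function(t) {
    t[c("prob", "statistic", "df", "p_value", "mean_delta")]
  })
  write_stats_json(list(tails = tails, n_experiments = res$n_experiments),
                   file.path(out_dir, "tmrm_test.json"))
  pipeline_log(log, "tmrm:", n_exp, "experiments x",
               cfg$n_events, "events")
}

run_stage_flux <- function(cfg, params, seed, out_dir, log) {
  tab <- gen_isotopomer_table(cfg, seed = seed)
  pb <- pca_biplot(tab)
  mt <- moderated_group_test(tab)
  write_table_csv(data.frame(sample = rownames(pb$scores),
                             genotype = pb$genotype,
                             pb$scores[, 1:2, drop = FALSE]),
                  file.path(out_dir, "flux_scores.csv"))
  write_table_csv(data.frame(feature = rownames(pb$loadings),
                             pb$loadings[, 1:2, drop = FALSE]),
                  file.path(out_dir, "flux_loadings.csv"))
  write_table_csv(mt, file.path(out_dir, "flux_test.csv"))
  write_stats_json(list(variance_explained = pb$variance_explained,
                        silhouette_pc1 = silhouette_width(pb),
                        prior_df = attr(mt, "d0"),
                        prior_variance = attr(mt, "s02")),
                   file.path(out_dir, "flux.json"))
  pipeline_log(log, "flux:", ncol(pb$loadings), "features,",
               nrow(pb$scores), "samples")
}

run_stage_emcounts <- function(cfg, params, seed, out_dir, log) {
  counts <- gen_field_counts(cfg, seed = seed)
  write_table_csv(counts, file.path(out_dir, "em_counts.csv"))
  av <- proportion_anova(counts)
  write_stats_json(list(anova = av), file.path(out_dir, "em_anova.json"))
  pipeline_log(log, "emcounts:", nrow(counts), "fields, p =",
               signif(av$p_value[1], 3))
}

#' Execute a run manifest
#'
#' Runs the manifest's stages in order, writing every table as CSV and
#' every statistic as JSON under `out_dir`, a stage-level `run.log` with
#' record counts, and `provenance.json` echoing the manifest plus the
#' package version and md5 hash of every tracked output. All randomness
#' derives from the manifest seed via [split_seed()], so re-executing a
#' manifest reproduces byte-identical CSV/JSON outputs.
#'
#' @param manifest manifest path or list (see [read_manifest()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the provenance list.
#' @export
run_pipeline <- function(manifest, out_dir) {
  manifest <- read_manifest(manifest)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out_dir, "run.log")
  if (file.exists(log)) file.remove(log)
  runners <- list(mito = run_stage_mito, droplets = run_stage_droplets,
                  tmrm = run_stage_tmrm, flux = run_stage_flux,
                  emcounts = run_stage_emcounts)
  for (i in seq_along(manifest$stages)) {
    st <- manifest$stages[[i]]
    params <- st$params %||% list()
    cfg <- stage_config(manifest, params)
    seed <- split_seed(manifest$seed, i)
    pipeline_log(log, "stage", i, "(", st$stage, ") start, seed", seed)
    ok <- tryCatch({
      runners[[st$stage]](cfg, params, seed, out_dir, log)
      TRUE
    }, error = function(e) {
      pipeline_log(log, "stage", i, "(", st$stage, ") FAILED:",
                   conditionMessage(e))
      stop("stage '", st$stage, "' failed: ", conditionMessage(e),
           " (partial outputs flagged in run.log)", call. = FALSE)
    })
  }
  outputs <- setdiff(list.files(out_dir), c("run.log", "provenance.json"))
  hashes <- as.list(tools::md5sum(file.path(out_dir, outputs)))
  names(hashes) <- outputs
  prov <- list(manifest = manifest,
               package_version = as.character(utils::packageVersion("mitomorph")),
               outputs = hashes)
  write_stats_json(prov, file.path(out_dir, "provenance.json"))
  invisible(prov)
}

#' Validate a table against a named schema
#'
#' Checks required columns, types and the domain invariants of the
#' corresponding table kind, returning every violation rather than just
#' the first.
#'
#' @param x data.frame or CSV path.
#' @param schema one of `"event_table"`, `"isotopomer_table"`,
#'   `"field_counts"`, `"object_features"`.
#' @return list with `ok` (logical) and `errors` (character vector of
#'   all violations).
#' @export
validate_table <- function(x, schema = c("event_table", "isotopomer_table",
                                         "field_counts", "object_features")) {
  schema <- match.arg(schema)
  if (is.character(x)) x <- read_table_csv(x)
  errs <- character(0)
  need <- function(cols) {
    miss <- setdiff(cols, names(x))
    if (length(miss)) {
      errs <<- c(errs, paste0("missing column(s): ",
                              paste(miss, collapse = ", ")))
      return(FALSE)
    }
    TRUE
  }
  if (schema == "event_table") {
    if (need(c("fsc", "ssc", "tmrm_raw"))) {
      for (col in c("fsc", "ssc", "tmrm_raw")) {
        if (!is.numeric(x[[col]])) {
          errs <- c(errs, paste0(col, " must be numeric"))
        } else if (any(x[[col]] <= 0 | !is.finite(x[[col]]))) {
          errs <- c(errs, paste0(col, " must be strictly positive and ",
                                 "finite (log-scale acquisition)"))
        }
      }
      if (nrow(x) < 100) {
        errs <- c(errs, "fewer than 100 events: too few for centile analysis")
      }
    }
  } else if (schema == "isotopomer_table") {
    if (need("genotype")) {
      num <- names(x)[vapply(x, is.numeric, logical(1))]
      if (length(num) == 0) {
        errs <- c(errs, "no numeric isotopomer columns")
      } else {
        vals <- as.matrix(x[, num, drop = FALSE])
        if (any(vals < 0 | vals > 1)) {
          errs <- c(errs, "fractional abundances must lie in [0, 1]")
        }
        for (m in unique(feature_metabolite(num))) {
          cols <- num[feature_metabolite(num) == m]
          sums <- rowSums(x[, cols, drop = FALSE])
          bad <- abs(sums - 1) > 1e-6
          if (any(bad)) {
            errs <- c(errs, paste0("metabolite block '", m, "' sums to ",
                                   signif(sums[which(bad)[1]], 6),
                                   " (must be 1 within 1e-6)"))
          }
        }
      }
    }
  } else if (schema == "field_counts") {
    if (need(c("normal", "aberrant", "genotype"))) {
      for (col in c("normal", "aberrant")) {
        if (any(x[[col]] < 0 | x[[col]] != round(x[[col]]))) {
          errs <- c(errs, paste0(col, " must be a nonnegative integer count"))
        }
      }
    }
  } else if (schema == "object_features") {
    if (need(c("label", "area_px", "convex_area_px", "solidity"))) {
      if (any(x$area_px < 1)) errs <- c(errs, "area_px must be >= 1")
      if (any(x$convex_area_px < x$area_px)) {
        errs <- c(errs, "convex_area_px must be >= area_px")
      }
      if (any(x$solidity <= 0 | x$solidity > 1)) {
        errs <- c(errs, "solidity must lie in (0, 1]")
      }
    }
  }
  list(ok = length(errs) == 0, errors = errs)
}
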