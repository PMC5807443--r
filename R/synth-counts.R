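## Synthetic electron-microscopy field counts: per randomly selected
## field, the number of mitochondria scored normal vs aberrant.

#' Generate synthetic per-field aberrant-mitochondria counts
#'
#' Per genotype and field, the total number of mitochondria is Poisson
#' (mean `mean_total`, floored at 1) and the aberrant count is binomial
#' with the genotype's planted probability.
#'
#' @param config a [synth_config()]; uses `n_fields` (fields per
#'   condition, default 30) and `p_aberrant_by_genotype`.
#' @param seed random seed.
#' @param cell_source label for the cell source (analyses are fitted
#'   within cell source).
#' @param mean_total Poisson mean of mitochondria per field.
#' @return data.frame with `cell_source`, `genotype`, `field`, `normal`,
#'   `aberrant`; planted probabilities in the `"truth"` attribute.
#' @export
gen_field_counts <- function(config = synth_config(), seed = config$seed,
                             cell_source = "line1", mean_total = 30) {
  if (config$n_fields < 2) stop("need >= 2 fields per condition")
  p <- config$p_aberrant_by_genotype
  if (any(p < 0 | p > 1)) stop("aberrant probabilities must be in [0, 1]")
  withr::with_seed(seed, {
    rows <- lapply(names(p), function(g) {
      tot <- pmax(1L, stats::rpois(config$n_fields, mean_total))
      ab <- stats::rbinom(config$n_fields, tot, p[[g]])
      data.frame(cell_source = cell_source, genotype = g,
                 field = seq_len(config$n_fields),
                 normal = tot - ab, aberrant = ab)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(p_aberrant = p)
    out
  })
}
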