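## Synthetic isotopomer fractional-abundance tables. Within each
## metabolite, the mass-isotopomer fractions of one sample are a
## Dirichlet draw; planted metabolites get a genotype-dependent tilt of
## the Dirichlet concentrations that moves labelling mass from low to
## high isotopomers.

flux_metabolite_set <- function() {
  list(pyruvate = 4L, lactate = 4L, citrate = 7L, alpha_kg = 6L,
       malate = 5L, aspartate = 5L, glutamate = 6L, succinate = 5L)
}

#' Generate a synthetic isotopomer table
#'
#' Rows are samples (default three replicates per genotype), columns are
#' (metabolite, isotopomer-mass) fractional abundances. Fractions within
#' each (sample, metabolite) block sum to 1. For metabolites in
#' `config$planted_metabolites`, mutant samples draw from Dirichlet
#' concentrations tilted by `exp(effect_size * d)` where `d` ramps from
#' -0.5 (M+0) to +0.5 (highest mass): a shift of labelled mass toward
#' heavier isotopomers.
#'
#' @param config a [synth_config()].
#' @param seed random seed.
#' @return data.frame of class `"isotopomer_table"`: column `genotype`
#'   plus one numeric column per `<metabolite>_M<k>` feature. Planted
#'   metabolites and effect size are stored in the `"truth"` attribute.
#' @export
gen_isotopomer_table <- function(config = synth_config(), seed = config$seed) {
  mets <- flux_metabolite_set()
  if (config$n_samples_per_group < 2) stop("need >= 2 samples per group")
  if (length(mets) < 4) stop("need >= 4 metabolites")
  if (!all(config$planted_metabolites %in% names(mets))) {
    stop("planted_metabolites must be a subset of: ",
         paste(names(mets), collapse = ", "))
  }
  if (config$effect_size < 0) stop("effect_size must be >= 0")
  withr::with_seed(seed, {
    n_per <- config$n_samples_per_group
    genotype <- rep(c("control", "mutant"), each = n_per)
    blocks <- lapply(names(mets), function(m) {
      k <- mets[[m]]
      w <- exp(-0.6 * (0:(k - 1)))               # labelling tails off with mass
      alpha0 <- 40 * w / sum(w)
      d <- seq(-0.5, 0.5, length.out = k)
      tilt <- if (m %in% config$planted_metabolites)
        exp(config$effect_size * d) else rep(1, k)
      vals <- t(vapply(genotype, function(g) {
        a <- if (g == "mutant") alpha0 * tilt else alpha0
        x <- stats::rgamma(k, shape = a, rate = 1)
        x / sum(x)
      }, numeric(k)))
      colnames(vals) <- paste0(m, "_M", 0:(k - 1))
      vals
    })
    out <- data.frame(genotype = genotype, do.call(cbind, blocks),
                      check.names = FALSE)
    rownames(out) <- paste0(genotype, "_", rep(seq_len(n_per), 2))
    attr(out, "truth") <- list(planted_metabolites = config$planted_metabolites,
                               effect_size = config$effect_size)
    class(out) <- c("isotopomer_table", "data.frame")
    out
  })
}

#' Metabolite of each isotopomer feature column
#'
#' Parses `<metabolite>_M<k>` feature names back to their metabolite.
#' @param features character vector of feature names.
#' @return character vector of metabolite names.
#' @export
feature_metabolite <- function(features) {
  sub("_M[0-9]+$", "", features)
}
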