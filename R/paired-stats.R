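## Figure-level statistics built on the quantile framework: the
## 25th-centile solidity fragmentation contrast, the transfection rescue
## delta, the droplet median-area test, the aberrant-proportion ANOVA,
## and the generic group tests.

#' Mitochondrial fragmentation statistic
#'
#' Per experiment and condition, the q-quantile (default 25th centile) of
#' per-object solidity; across experiments, a paired t-test of mutant vs
#' matched control. Higher values correspond to a more fragmented
#' network.
#'
#' @param features data.frame of object features with columns `solidity`,
#'   `experiment_id` and `condition` (values `"control"`/`"mutant"`).
#' @param q quantile of the solidity distribution (default 0.25).
#' @return list with `per_experiment` (experiment, control, mutant,
#'   delta), `statistic`, `df`, `p_value`, `q`.
#' @export
fragmentation_stat <- function(features, q = 0.25) {
  stopifnot(all(c("solidity", "experiment_id", "condition") %in% names(features)))
  exps <- unique(features$experiment_id)
  per <- lapply(exps, function(e) {
    sub <- features[features$experiment_id == e, ]
    for (cond in c("control", "mutant")) {
      if (!any(sub$condition == cond)) {
        stop("experiment ", e, " is missing its ", cond, " arm")
      }
    }
    data.frame(
      experiment_id = e,
      control = empirical_quantile(sub$solidity[sub$condition == "control"], q),
      mutant = empirical_quantile(sub$solidity[sub$condition == "mutant"], q)
    )
  })
  per <- do.call(rbind, per)
  per$delta <- per$mutant - per$control
  tt <- delta_t_test(per$delta)
  list(per_experiment = per, statistic = tt$t, df = tt$df, p_value = tt$p,
       q = q)
}

#' Transfection rescue delta
#'
#' Within each experiment, delta = q-quantile solidity of transfected
#' cells minus untransfected cells; a more elongated transfected network
#' gives a negative delta. Deltas are then compared between the two
#' plasmid arms (e.g. the construct of interest vs a
#' mitochondrially-targeted control) with a paired t-test across matched
#' experiments sharing an `experiment_id`.
#'
#' @param features data.frame with columns `solidity`, `experiment_id`,
#'   `plasmid` (exactly two levels) and `transfected` (logical).
#' @param q solidity quantile (default 0.25).
#' @return list with `deltas` (experiment x plasmid delta table),
#'   `statistic`, `df`, `p_value`, `plasmids`.
#' @export
rescue_delta <- function(features, q = 0.25) {
  stopifnot(all(c("solidity", "experiment_id", "plasmid", "transfected")
                %in% names(features)))
  plasmids <- sort(unique(features$plasmid))
  if (length(plasmids) != 2) stop("exactly two plasmid arms are required")
  key <- interaction(features$experiment_id, features$plasmid, drop = TRUE)
  per <- lapply(split(features, key), function(sub) {
    if (!any(sub$transfected) || !any(!sub$transfected)) {
      stop("experiment ", sub$experiment_id[1], " / plasmid ",
           sub$plasmid[1], " lacks a transfected or untransfected arm")
    }
    data.frame(
      experiment_id = sub$experiment_id[1], plasmid = sub$plasmid[1],
      delta = empirical_quantile(sub$solidity[sub$transfected], q) -
        empirical_quantile(sub$solidity[!sub$transfected], q)
    )
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  wide <- stats::reshape(per, idvar = "experiment_id", timevar = "plasmid",
                         direction = "wide")
  if (any(is.na(wide))) stop("plasmid arms are not matched across experiments")
  d <- wide[[paste0("delta.", plasmids[1])]] -
    wide[[paste0("delta.", plasmids[2])]]
  tt <- delta_t_test(d)
  list(deltas = per, statistic = tt$t, df = tt$df, p_value = tt$p,
       plasmids = plasmids, q = q)
}

#' Paired test of median droplet area
#'
#' Per experiment and condition, the median droplet area; across
#' experiments, a paired t-test mutant vs control. Also returns the
#' per-experiment quantile curves for plotting (optionally truncated,
#' e.g. to the 80th quantile, to highlight the lower range).
#'
#' @param areas data.frame with columns `area`, `experiment_id`,
#'   `condition` (`"control"`/`"mutant"`).
#' @return list with `per_experiment`, `statistic`, `df`, `p_value`,
#'   `curves` (a `"quantile_curve"` data.frame per experiment/condition).
#' @export
median_area_test <- function(areas) {
  stopifnot(all(c("area", "experiment_id", "condition") %in% names(areas)))
  exps <- unique(areas$experiment_id)
  per <- list(); curves <- list()
  for (e in exps) {
    for (cond in c("control", "mutant")) {
      a <- areas$area[areas$experiment_id == e & areas$condition == cond]
      if (length(a) == 0) {
        stop("experiment ", e, " has no droplets in its ", cond, " arm")
      }
      curves[[paste(e, cond, sep = ".")]] <-
        quantile_curve(a, group = paste(e, cond, sep = "."))
      per[[paste(e, cond, sep = ".")]] <-
        data.frame(experiment_id = e, condition = cond,
                   median_area = stats::median(a))
    }
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  wide <- stats::reshape(per, idvar = "experiment_id", timevar = "condition",
                         direction = "wide")
  if (nrow(wide) < 2) stop("need >= 2 paired experiments")
  d <- wide$median_area.mutant - wide$median_area.control
  tt <- delta_t_test(d)
  list(per_experiment = per, statistic = tt$t, df = tt$df, p_value = tt$p,
       curves = do.call(rbind, curves))
}

#' One-way ANOVA of aberrant-mitochondria proportion on genotype
#'
#' Per field, the proportion aberrant = aberrant / (normal + aberrant);
#' a one-way ANOVA of proportion on genotype is fitted separately within
#' each cell source. Zero-total fields are excluded with a warning. When
#' every field shares one proportion the contract is F = 0, p = 1.
#'
#' @param counts data.frame with columns `normal`, `aberrant`,
#'   `genotype` and optionally `cell_source` (single source assumed if
#'   absent).
#' @return data.frame with one row per cell source: `cell_source`, `F`,
#'   `df1`, `df2`, `p_value`, `n_fields`.
#' @export
proportion_anova <- function(counts) {
  stopifnot(all(c("normal", "aberrant", "genotype") %in% names(counts)))
  if (is.null(counts$cell_source)) counts$cell_source <- "all"
  tot <- counts$normal + counts$aberrant
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-total field(s) excluded")
    counts <- counts[tot > 0, ]
    tot <- tot[tot > 0]
  }
  counts$prop <- counts$aberrant / tot
  res <- lapply(split(counts, counts$cell_source), function(sub) {
    tab <- table(sub$genotype)
    if (any(tab < 2)) stop("need >= 2 fields per genotype within each cell source")
    g <- length(tab); n <- nrow(sub)
    if (stats::var(sub$prop) == 0) {
      return(data.frame(cell_source = sub$cell_source[1], F = 0,
                        df1 = g - 1, df2 = n - g, p_value = 1, n_fields = n))
    }
    fit <- stats::aov(prop ~ genotype, data = sub)
    s <- summary(fit)[[1]]
    data.frame(cell_source = sub$cell_source[1], F = s$`F value`[1],
               df1 = s$Df[1], df2 = s$Df[2], p_value = s$`Pr(>F)`[1],
               n_fields = n)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Generic two-group tests
#'
#' The standard two-sided tests used for whole-organism phenotype
#' tables: a two-sample t-test on per-experiment fractions
#' (`"fraction_t"`), a Wilcoxon rank-sum test on counts (`"rank_sum"`;
#' exact when both groups have <= 10 untied observations, normal
#' approximation with tie correction otherwise), and a paired t-test
#' (`"paired_t"`, pairing by `pair_id`).
#'
#' @param data data.frame with columns `value`, `group` (two levels) and,
#'   for the paired test, `pair_id`.
#' @param test which test to run.
#' @return list with `statistic`, `p_value`, `method` and, for t-tests,
#'   `df`.
#' @export
group_tests <- function(data, test = c("fraction_t", "rank_sum", "paired_t")) {
  test <- match.arg(test)
  stopifnot(all(c("value", "group") %in% names(data)))
  groups <- sort(unique(as.character(data$group)))
  if (length(groups) != 2) stop("exactly two groups are required")
  x <- data$value[data$group == groups[1]]
  y <- data$value[data$group == groups[2]]
  if (test == "fraction_t") {
    if (any(data$value < 0 | data$value > 1)) {
      stop("fraction_t expects values in [0, 1]")
    }
    if (stats::sd(c(x, y)) == 0) {
      return(list(statistic = 0, df = length(x) + length(y) - 2,
                  p_value = 1, method = "two-sample t on fractions"))
    }
    ht <- stats::t.test(x, y)
    return(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value, method = "two-sample t on fractions"))
  }
  if (test == "rank_sum") {
    exact <- length(x) <= 10 && length(y) <= 10 &&
      !any(duplicated(c(x, y)))
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                              correct = TRUE))
    return(list(statistic = unname(ht$statistic), p_value = ht$p.value,
                method = if (exact) "exact rank-sum"
                else "rank-sum, normal approximation with tie correction"))
  }
  # paired_t
  if (is.null(data$pair_id)) stop("paired_t requires a pair_id column")
  xi <- data[data$group == groups[1], ]
  yi <- data[data$group == groups[2], ]
  if (!setequal(xi$pair_id, yi$pair_id) || anyDuplicated(xi$pair_id) ||
      anyDuplicated(yi$pair_id)) {
    stop("pairing violation: pair_id must match one-to-one across groups")
  }
  d <- xi$value[order(xi$pair_id)] - yi$value[order(yi$pair_id)]
  tt <- delta_t_test(d)
  list(statistic = tt$t, df = tt$df, p_value = tt$p, method = "paired t")
}
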