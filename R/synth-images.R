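## Synthetic fluorescence fields with planted ground truth. Tubules are
## correlated random-walk skeletons dilated to ~3 px width; fragments and
## lipid droplets are discs. Noise = Poisson shot noise on the clean
## intensity plus Gaussian background.

## Pixel offsets of a tubule: correlated random walk, 3x3 dilation.
draw_tubule_px <- function(length_px, curvature) {
  n <- max(2L, round(length_px))
  heading <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n - 1, 0, curvature)))
  r <- round(cumsum(sin(heading)))
  c <- round(cumsum(cos(heading)))
  off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  px <- unique(cbind(rep(r, each = 9L) + off[, 1],
                     rep(c, each = 9L) + off[, 2]))
  px
}

## Pixel offsets of a disc of radius r (pixel centers within r).
draw_disc_px <- function(radius) {
  rr <- ceiling(radius)
  g <- as.matrix(expand.grid(dr = -rr:rr, dc = -rr:rr))
  g[g[, 1]^2 + g[, 2]^2 <= radius^2, , drop = FALSE]
}

## Place object pixel sets into an image without overlap (1-px halo keeps
## components 8-disconnected). Returns the label matrix and truth table,
## or errors if placement cannot terminate.
place_objects <- function(px_list, shape, max_attempts = 300L) {
  lab <- matrix(0L, shape[1], shape[2])
  occ <- matrix(FALSE, shape[1], shape[2])
  for (k in seq_along(px_list)) {
    px <- px_list[[k]]
    px[, 1] <- px[, 1] - min(px[, 1])          # 0-based local coords
    px[, 2] <- px[, 2] - min(px[, 2])
    h <- max(px[, 1]) + 1L; w <- max(px[, 2]) + 1L
    if (h + 2L > shape[1] || w + 2L > shape[2]) {
      stop("object of extent ", h, "x", w, " does not fit the image")
    }
    placed <- FALSE
    for (a in seq_len(max_attempts)) {
      r0 <- sample.int(shape[1] - h - 1L, 1L) + 1L
      c0 <- sample.int(shape[2] - w - 1L, 1L) + 1L
      rows <- (r0 - 1L):(r0 + h)               # bounding box + 1 px halo
      cols <- (c0 - 1L):(c0 + w)
      if (!any(occ[rows, cols])) {
        idx <- cbind(r0 + px[, 1], c0 + px[, 2])
        lab[idx] <- k
        occ[rows, cols] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("object placement did not terminate after ", max_attempts,
           " attempts; attempted density: ", length(px_list),
           " objects in a ", shape[1], "x", shape[2], " field")
    }
  }
  lab
}

## Clean intensity image from a label map, then Poisson + Gaussian noise.
render_field <- function(lab, background_level, background_sigma,
                         photon_scale, amp_range = c(350, 650)) {
  k <- max(lab)
  amps <- if (k > 0) stats::runif(k, amp_range[1], amp_range[2]) else numeric(0)
  clean <- matrix(background_level, nrow(lab), ncol(lab))
  if (k > 0) clean[lab > 0] <- background_level + amps[lab[lab > 0]]
  img <- clean
  if (is.finite(photon_scale)) {
    img <- matrix(stats::rpois(length(clean), clean * photon_scale) / photon_scale,
                  nrow(clean), ncol(clean))
  }
  if (background_sigma > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, background_sigma),
                        nrow(img), ncol(img))
  }
  pmax(img, 0)
}

#' Generate a synthetic mitochondrial field
#'
#' Draws `n_objects_per_field` objects — each a compact disc (with
#' probability `fragmentation`) or an elongated random-walk tubule —
#' places them without overlap, and renders an intensity image with
#' Poisson shot noise and Gaussian background. The noiseless ground-truth
#' label map and per-object classes are returned alongside.
#'
#' @param config a [synth_config()].
#' @param fragmentation fraction of fragment (disc) objects; defaults to
#'   the config value.
#' @param seed random seed; defaults to the config value.
#' @return list of class `"mito_field"` with `image` (intensity matrix),
#'   `labels` (truth label matrix), `truth` (data.frame: label, class,
#'   area_px), and the generating `fragmentation` and `seed`.
#' @export
gen_mito_field <- function(config = synth_config(),
                           fragmentation = config$fragmentation,
                           seed = config$seed) {
  if (fragmentation < 0 || fragmentation > 1)
    stop("fragmentation must be in [0, 1]")
  withr::with_seed(seed, {
    n <- config$n_objects_per_field
    is_frag <- stats::runif(n) < fragmentation
    px_list <- lapply(seq_len(n), function(i) {
      if (is_frag[i]) draw_disc_px(config$fragment_radius_px)
      else draw_tubule_px(config$tubule_length_px, config$tubule_curvature)
    })
    lab <- place_objects(px_list, config$image_shape)
    img <- render_field(lab, background_level = 50,
                        background_sigma = config$background_sigma,
                        photon_scale = config$photon_scale)
    truth <- data.frame(
      label = seq_len(n),
      class = ifelse(is_frag, "fragment", "tubule"),
      area_px = as.integer(tabulate(lab[lab > 0], nbins = n))
    )
    structure(list(image = img, labels = lab, truth = truth,
                   fragmentation = fragmentation, seed = seed),
              class = "mito_field")
  })
}

#' Generate a multi-field mitochondrial experiment
#'
#' Fields are seeded via [split_seed()] so each is reproducible in
#' isolation. Default 50 fields of ~16 objects emulate one imaging
#' experiment of roughly 800 analysed mitochondria.
#'
#' @inheritParams gen_mito_field
#' @param n_fields number of fields.
#' @return list of `"mito_field"` objects.
#' @export
gen_mito_experiment <- function(config = synth_config(),
                                fragmentation = config$fragmentation,
                                n_fields = 50, seed = config$seed) {
  lapply(seq_len(n_fields), function(k) {
    gen_mito_field(config, fragmentation, seed = split_seed(seed, k))
  })
}

#' Generate an object population with shape features, skipping the image
#'
#' Draws object shapes exactly as [gen_mito_field()] would and computes
#' their shape features directly from the truth masks, without field
#' placement or rendering. This is the scalable route for statistical
#' simulations that only need per-object solidity.
#'
#' @inheritParams gen_mito_field
#' @param n_objects number of objects to draw.
#' @return data.frame with `label`, `class`, `area_px`, `convex_area_px`,
#'   `solidity`.
#' @export
gen_object_population <- function(config = synth_config(),
                                  fragmentation = config$fragmentation,
                                  n_objects = 100, seed = config$seed) {
  if (fragmentation < 0 || fragmentation > 1)
    stop("fragmentation must be in [0, 1]")
  withr::with_seed(seed, {
    is_frag <- stats::runif(n_objects) < fragmentation
    res <- lapply(seq_len(n_objects), function(i) {
      px <- if (is_frag[i]) draw_disc_px(config$fragment_radius_px)
      else draw_tubule_px(config$tubule_length_px, config$tubule_curvature)
      c(area = nrow(px), conv = raster_hull_count(px))
    })
    m <- do.call(rbind, res)
    data.frame(label = seq_len(n_objects),
               class = ifelse(is_frag, "fragment", "tubule"),
               area_px = m[, "area"],
               convex_area_px = m[, "conv"],
               solidity = m[, "area"] / m[, "conv"])
  })
}

#' Generate a synthetic lipid-droplet field
#'
#' Circular droplets with lognormal areas; `area_scale` multiplies the
#' area scale (mutant fields use `area_scale > 1`). The truth vector
#' holds the realized pixel area of each droplet, so on a noiseless
#' rendering segmentation recovers it exactly.
#'
#' @inheritParams gen_mito_field
#' @param area_scale positive multiplicative factor on droplet area.
#' @param render render the noisy intensity image (`TRUE`, default);
#'   `FALSE` skips rendering and returns `image = NULL` for simulations
#'   that only consume the truth label map and areas.
#' @return list of class `"droplet_field"` with `image`, `labels`,
#'   `truth_areas` (px^2 per droplet) and `seed`.
#' @export
gen_droplet_field <- function(config = synth_config(), area_scale = 1,
                              seed = config$seed, render = TRUE) {
  if (area_scale <= 0) stop("area_scale must be > 0")
  withr::with_seed(seed, {
    n <- config$droplet_density
    if (n == 0L) {
      lab <- matrix(0L, config$image_shape[1], config$image_shape[2])
      img <- if (render) render_field(lab, 50, config$background_sigma,
                                      config$photon_scale)
      return(structure(list(image = img, labels = lab,
                            truth_areas = numeric(0), seed = seed),
                       class = "droplet_field"))
    }
    max_area <- pi * (min(config$image_shape) / 6)^2
    areas <- pmin(stats::rlnorm(n, config$droplet_log_area_mu + log(area_scale),
                                config$droplet_log_area_sigma), max_area)
    px_list <- lapply(sqrt(areas / pi), draw_disc_px)
    lab <- place_objects(px_list, config$image_shape)
    img <- if (render) render_field(lab, 50, config$background_sigma,
                                    config$photon_scale)
    structure(list(image = img, labels = lab,
                   truth_areas = as.integer(tabulate(lab[lab > 0], nbins = n)),
                   seed = seed),
              class = "droplet_field")
  })
}

#' Generate a multi-field droplet experiment's truth areas
#'
#' The droplet-size protocol samples 10 random fields per experiment;
#' this helper draws that many fields (seeded via [split_seed()]) and
#' pools their truth areas.
#'
#' @inheritParams gen_droplet_field
#' @param n_fields fields per experiment (default 10).
#' @return numeric vector of pooled truth areas (px^2).
#' @export
gen_droplet_experiment_areas <- function(config = synth_config(),
                                         area_scale = 1, n_fields = 10,
                                         seed = config$seed) {
  unlist(lapply(seq_len(n_fields), function(k) {
    gen_droplet_field(config, area_scale, seed = split_seed(seed, k),
                      render = FALSE)$truth_areas
  }))
}
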