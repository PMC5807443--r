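## Segmentation of mitochondria and lipid droplets: global threshold
## (Otsu by default), 8-connected components, area and border filters.

#' 8-connected component labelling
#'
#' EBImage's labeller is 4-connected; diagonal contacts between thin
#' tubule segments must not split an object, so labels that touch
#' diagonally are merged with a union-find pass and the result is
#' relabelled 1..K in raster-scan (row-major) order of each component's
#' first pixel.
#' @param fg logical or 0/1 matrix.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components8 <- function(fg) {
  fg <- matrix(as.numeric(fg != 0), nrow(fg), ncol(fg))
  lab <- EBImage::imageData(EBImage::bwlabel(fg))
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  k <- max(lab)
  if (k > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # down-right diagonal
    a2 <- lab[-1, -nc];  b2 <- lab[-nr, -1]   # up-right diagonal
    s1 <- a1 > 0L & b1 > 0L & a1 != b1
    s2 <- a2 > 0L & b2 > 0L & a2 != b2
    pa <- c(a1[s1], a2[s2]); pb <- c(b1[s1], b2[s2])
    if (length(pa)) {
      parent <- seq_len(k)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (j in seq_along(pa)) {
        ra <- find(pa[j]); rb <- find(pb[j])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(k), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  relabel_raster_order(lab)
}

## Renumber surviving labels 1..K by row-major position of each
## component's first pixel; guarantees a gap-free, deterministic label set.
relabel_raster_order <- function(lab) {
  ids <- unique(lab[lab > 0L])
  if (length(ids) == 0L) return(lab)
  nr <- nrow(lab)
  pos <- which(lab > 0L)                        # column-major indices
  rows <- (pos - 1L) %% nr + 1L
  cols <- (pos - 1L) %/% nr + 1L
  raster <- (rows - 1L) * ncol(lab) + cols      # row-major rank
  first <- tapply(raster, lab[pos], min)
  ord <- order(first)
  map <- integer(max(ids))
  map[as.integer(names(first))[ord]] <- seq_along(ord)
  lab[pos] <- map[lab[pos]]
  lab
}

#' Otsu threshold of an intensity image
#'
#' Thin wrapper around EBImage's Otsu implementation, rescaled to the
#' image's own intensity range.
#' @param image numeric matrix of finite intensities.
#' @return scalar threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) stop("constant image has no Otsu threshold")
  x <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256)
  rng[1] + th * diff(rng)
}

#' Segment objects from a fluorescence channel
#'
#' Foreground = pixels above the computed (Otsu, default) or supplied
#' fixed threshold; 8-connected components; components smaller than
#' `min_area` removed; optionally components touching the image border
#' removed; survivors relabelled 1..K in raster-scan order.
#'
#' A constant image (or one whose threshold leaves no foreground) yields
#' an empty label map with a warning — no objects is a result, not a
#' failure. Non-finite pixels are an error.
#'
#' @param image numeric matrix, or a generated field carrying `$image`.
#' @param min_area minimum object area in pixels (default 10 for
#'   mitochondria: smaller specks are below the scale at which the
#'   solidity index is meaningful).
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param exclude_border drop components touching the image edge
#'   (default FALSE; kept unless requested).
#' @return integer label matrix (0 = background).
#' @export
segment_objects <- function(image, min_area = 10, threshold = "otsu",
                            exclude_border = FALSE) {
  if (is.list(image) && !is.null(image$image)) image <- image$image
  if (!is.matrix(image) || length(image) == 0) stop("image must be a nonempty matrix")
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  if (min_area < 1) stop("min_area must be >= 1")
  if (is.character(threshold)) {
    threshold <- match.arg(threshold, "otsu")
    if (diff(range(image)) == 0) {
      warning("constant image: no foreground found, returning empty label map")
      return(matrix(0L, nrow(image), ncol(image)))
    }
    thr <- otsu_threshold(image)
  } else {
    thr <- as.numeric(threshold)
  }
  fg <- image > thr
  if (!any(fg)) {
    warning("no pixels above threshold: returning empty label map")
    return(matrix(0L, nrow(image), ncol(image)))
  }
  lab <- label_components8(fg)
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_area)
    if (length(drop)) lab[lab %in% drop] <- 0L
    if (exclude_border) {
      edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
      edge <- edge[edge > 0L]
      if (length(edge)) lab[lab %in% edge] <- 0L
    }
    lab <- relabel_raster_order(lab)
  }
  lab
}

#' Match segmented objects to ground-truth objects by overlap
#'
#' Greedy one-to-one matching of label pairs by decreasing intersection
#' over union (IoU); used to benchmark segmentation against a
#' generator's truth label map.
#'
#' @param truth,segmented integer label matrices of the same shape.
#' @param min_iou minimum IoU for a pair to count as matched.
#' @return data.frame with one row per truth object: `truth_label`,
#'   `seg_label` (NA if unmatched), `iou`.
#' @export
match_labels <- function(truth, segmented, min_iou = 0.5) {
  if (!all(dim(truth) == dim(segmented))) stop("label maps must share shape")
  both <- truth > 0L & segmented > 0L
  t_area <- tabulate(truth[truth > 0L])
  s_area <- tabulate(segmented[segmented > 0L])
  out <- data.frame(truth_label = seq_along(t_area),
                    seg_label = NA_integer_, iou = 0)
  if (any(both)) {
    inter <- table(truth = truth[both], seg = segmented[both])
    pairs <- as.data.frame(inter, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$Freq > 0, ]
    ti <- as.integer(pairs$truth); si <- as.integer(pairs$seg)
    iou <- pairs$Freq / (t_area[ti] + s_area[si] - pairs$Freq)
    ord <- order(-iou)
    used_t <- logical(length(t_area)); used_s <- logical(length(s_area))
    for (k in ord) {
      if (iou[k] < min_iou) break
      i <- ti[k]; j <- si[k]
      if (!used_t[i] && !used_s[j]) {
        used_t[i] <- TRUE; used_s[j] <- TRUE
        out$seg_label[i] <- j; out$iou[i] <- iou[k]
      }
    }
  }
  out
}

#' Segment lipid droplets
#'
#' [segment_objects()] with droplet defaults: a smaller minimum area
#' (droplets can be compact), automatic Otsu threshold standing in for
#' the blinded manual threshold used at the microscope.
#' @inheritParams segment_objects
#' @export
segment_droplets <- function(image, min_area = 4, threshold = "otsu",
                             exclude_border = FALSE) {
  segment_objects(image, min_area = min_area, threshold = threshold,
                  exclude_border = exclude_border)
}
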