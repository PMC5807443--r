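## Shape features for segmented objects. The central quantity is the
## solidity index: object area divided by the area of its convex hull.
## Connected (tubular, branched) mitochondrial networks have low solidity;
## fragmented, disconnected mitochondria score higher.

#' Convert a mask matrix to pixel coordinates
#' @noRd
as_pixel_coords <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix (non-zero = object)")
  idx <- which(mask != 0, arr.ind = TRUE)
  cbind(row = idx[, 1], col = idx[, 2])
}

#' Check 8-connectivity of a pixel set
#' @noRd
is_connected8 <- function(px) {
  n <- nrow(px)
  if (n <= 1) return(TRUE)
  r0 <- min(px[, 1]) - 1L; c0 <- min(px[, 2]) - 1L
  nr <- max(px[, 1]) - r0 + 1L; nc <- max(px[, 2]) - c0 + 1L
  m <- matrix(FALSE, nr, nc)
  m[cbind(px[, 1] - r0, px[, 2] - c0)] <- TRUE
  lab <- label_components8(m)
  max(lab) == 1L
}

## Convex hull of the corner points of a pixel set. Every pixel (r, c)
## contributes its four corners (r +- 0.5, c +- 0.5), so the hull polygon
## follows the union-of-squares outline of the object. Returns the hull
## vertices (x = col, y = row) in chull order.
hull_corner_vertices <- function(px) {
  cx <- c(px[, 2] - 0.5, px[, 2] + 0.5, px[, 2] - 0.5, px[, 2] + 0.5)
  cy <- c(px[, 1] - 0.5, px[, 1] - 0.5, px[, 1] + 0.5, px[, 1] + 0.5)
  h <- grDevices::chull(cx, cy)
  list(x = cx[h], y = cy[h])
}

## Rasterized convex hull area of a pixel set: the number of pixels
## whose center lies strictly inside the corner-point hull polygon,
## union the object's own pixels. Hull vertices sit at half-integer
## coordinates, so integer scanlines never pass through a vertex or a
## horizontal edge and each scanline crosses exactly two edges. The
## strict-interior rule (centers exactly on a hull edge are excluded
## unless they belong to the object) reproduces the counts of the
## standard image-analysis tool chain; the object union guarantees
## hull area >= object area, i.e. solidity <= 1.
raster_hull_count <- function(px) {
  v <- hull_corner_vertices(px)
  vx <- v$x; vy <- v$y
  nv <- length(vx)
  x1 <- vx; y1 <- vy
  x2 <- vx[c(2:nv, 1)]; y2 <- vy[c(2:nv, 1)]
  keep <- y1 != y2
  x1 <- x1[keep]; y1 <- y1[keep]; x2 <- x2[keep]; y2 <- y2[keep]
  obj_rows <- split(px[, 2], px[, 1])
  total <- 0L
  for (y in ceiling(min(vy)):floor(max(vy))) {
    cross <- (y1 - y) * (y2 - y) < 0
    t <- (y - y1[cross]) / (y2[cross] - y1[cross])
    xs <- x1[cross] + t * (x2[cross] - x1[cross])
    lo <- ceiling(min(xs) + 1e-9); hi <- floor(max(xs) - 1e-9)
    n_in <- max(0L, hi - lo + 1L)
    orow <- obj_rows[[as.character(y)]]
    n_extra <- if (is.null(orow)) 0L else sum(orow < lo | orow > hi)
    total <- total + n_in + n_extra
  }
  as.integer(total)
}

shoelace_area <- function(vx, vy) {
  n <- length(vx)
  abs(sum(vx * vy[c(2:n, 1)] - vx[c(2:n, 1)] * vy)) / 2
}

#' Convex hull area of a connected pixel mask
#'
#' Computes the area of the smallest convex region enclosing an object,
#' under one of two conventions:
#' \describe{
#'   \item{`"raster"`}{the default, used for all reported solidity values:
#'     the convex hull polygon is built from the corner points of every
#'     object pixel (the union-of-squares outline) and the returned area
#'     is the number of pixels whose centers fall strictly inside that
#'     polygon, union the object's own pixels. This reproduces the hull
#'     pixel counts of the common image-analysis tool chain and
#'     guarantees hull area >= object area. Always an integer count, in
#'     px.}
#'   \item{`"polygon"`}{the exact-geometry oracle: the shoelace-formula
#'     area of the same corner-point hull polygon, in px^2. Used for
#'     testing the rasterized fast path against exact geometry.}
#' }
#' A filled rectangle has identical area under both conventions; small or
#' skinny objects differ because rasterization counts whole pixels.
#'
#' @param mask logical/numeric matrix (non-zero = object) or an n x 2
#'   integer matrix of (row, col) pixel coordinates.
#' @param convention `"raster"` (default) or `"polygon"`.
#' @return scalar area (integer pixel count for `"raster"`, numeric px^2
#'   for `"polygon"`).
#' @examples
#' m <- matrix(1, 5, 5)
#' convex_hull_area(m)                         # 25
#' convex_hull_area(m, convention = "polygon") # 25
#' @export
convex_hull_area <- function(mask, convention = c("raster", "polygon")) {
  convention <- match.arg(convention)
  px <- as_pixel_coords(mask)
  if (nrow(px) == 0) stop("mask is empty")
  if (!is_connected8(px)) {
    stop("mask is not 8-connected; objects must be single connected components")
  }
  hull_area_px(px, convention)
}

## Hull area from pixel coordinates (shared by the mask-facing API).
hull_area_px <- function(px, convention) {
  if (convention == "polygon") {
    v <- hull_corner_vertices(px)
    return(shoelace_area(v$x, v$y))
  }
  raster_hull_count(px)
}

#' Solidity of a connected pixel mask
#'
#' Area divided by convex hull area. Under the raster convention a
#' single-pixel object has solidity 1 (limit case of the ratio); filled
#' rectangles have solidity exactly 1.
#'
#' @inheritParams convex_hull_area
#' @return scalar in (0, 1] for `"raster"`; the `"polygon"` oracle can
#'   exceed small-object raster values because its hull area is exact.
#' @export
solidity <- function(mask, convention = c("raster", "polygon")) {
  convention <- match.arg(convention)
  px <- as_pixel_coords(mask)
  if (nrow(px) == 0) stop("mask is empty")
  if (!is_connected8(px)) {
    stop("mask is not 8-connected; objects must be single connected components")
  }
  nrow(px) / hull_area_px(px, convention)
}

#' Per-object shape features from a label map
#'
#' One record per labelled object: pixel area, rasterized convex hull
#' area, solidity, centroid and border contact, plus the experiment
#' metadata carried along for downstream paired statistics. Reported
#' solidity always uses the rasterized hull convention; `oracle = TRUE`
#' adds exact polygon-hull columns (`convex_area_exact`,
#' `solidity_exact`) for convergence studies.
#'
#' @param labels integer label matrix (0 = background, objects 1..K), or a
#'   segmentation result carrying `$labels`.
#' @param image optional intensity matrix of the same shape (checked, not
#'   otherwise used; shape features are intensity-free).
#' @param field_id,experiment_id,condition,cell_line metadata labels
#'   attached to every object row.
#' @param oracle add exact-geometry hull columns.
#' @return data.frame with columns `label`, `area_px`, `convex_area_px`,
#'   `solidity`, `centroid_row`, `centroid_col` (0-based), `touches_border`
#'   and the metadata columns.
#' @export
compute_features <- function(labels, image = NULL, field_id = NA,
                             experiment_id = NA, condition = NA,
                             cell_line = NA, oracle = FALSE) {
  if (is.list(labels) && !is.null(labels$labels)) labels <- labels$labels
  if (!is.matrix(labels)) stop("labels must be a matrix")
  if (!is.null(image)) {
    if (is.list(image) && !is.null(image$pixels)) image <- image$pixels
    if (!all(dim(image) == dim(labels))) {
      stop("labels and image must share the same shape")
    }
  }
  ids <- sort(unique(labels[labels > 0]))
  nr <- nrow(labels); nc <- ncol(labels)
  out <- vector("list", length(ids))
  idx_all <- which(labels > 0, arr.ind = TRUE)
  lab_all <- labels[labels > 0]
  for (i in seq_along(ids)) {
    px <- idx_all[lab_all == ids[i], , drop = FALSE]
    conv <- raster_hull_count(px)
    rec <- data.frame(
      label = ids[i],
      area_px = nrow(px),
      convex_area_px = conv,
      solidity = nrow(px) / conv,
      centroid_row = mean(px[, 1]) - 1,
      centroid_col = mean(px[, 2]) - 1,
      touches_border = any(px[, 1] == 1L | px[, 1] == nr |
                             px[, 2] == 1L | px[, 2] == nc),
      field_id = field_id, experiment_id = experiment_id,
      condition = condition, cell_line = cell_line
    )
    if (oracle) {
      v <- hull_corner_vertices(px)
      rec$convex_area_exact <- shoelace_area(v$x, v$y)
      rec$solidity_exact <- rec$area_px / rec$convex_area_exact
    }
    out[[i]] <- rec
  }
  if (length(out) == 0) {
    cols <- c("label", "area_px", "convex_area_px", "solidity",
              "centroid_row", "centroid_col", "touches_border",
              "field_id", "experiment_id", "condition", "cell_line")
    df <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  do.call(rbind, out)
}
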