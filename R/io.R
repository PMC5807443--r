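## Format plumbing: 16-bit grayscale TIFF for images and label maps, CSV
## with a header row for every table, JSON for statistics and provenance.

#' Write an intensity image as 16-bit grayscale TIFF
#'
#' Intensities are stored on a fixed 0..65535 scale: `max_value` maps to
#' 65535 (default: the image maximum, recorded so the image can be
#' rescaled on read).
#'
#' @param image numeric matrix of nonnegative intensities.
#' @param path output file.
#' @param max_value intensity mapped to full scale.
#' @return `max_value`, invisibly.
#' @export
write_channel_tiff <- function(image, path, max_value = max(image)) {
  if (max_value <= 0) max_value <- 1
  x <- pmin(pmax(image / max_value, 0), 1)
  tiff::writeTIFF(x, path, bits.per.sample = 16)
  invisible(max_value)
}

#' Read a grayscale TIFF as an intensity matrix
#'
#' @param path TIFF file.
#' @param max_value full-scale intensity (the `max_value` used at write).
#' @return numeric matrix.
#' @export
read_channel_tiff <- function(path, max_value = 1) {
  as.matrix(tiff::readTIFF(path)) * max_value
}

#' Write / read a label map as 16-bit TIFF
#'
#' Labels are stored as integer gray levels (0 = background); supports up
#' to 65535 objects.
#' @param labels integer matrix.
#' @param path file path.
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  m <- as.matrix(tiff::readTIFF(path))
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a table as CSV with a header row
#' @param x data.frame.
#' @param path output file.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a CSV table
#' @param path input file.
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}

#' Write statistics as JSON
#' @param x named list of results.
#' @param path output file.
#' @export
write_stats_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
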