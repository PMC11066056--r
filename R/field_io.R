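#' Multi-channel field image container and TIFF round-trip
#'
#' A `field_image` holds three co-registered non-negative intensity planes
#' (`dna`, `rrna`, `phage`) of equal dimensions plus the physical pixel
#' size. On disk a field is a multi-page grayscale TIFF, one page per
#' channel in the fixed order dna / rrna / phage (recorded in the image
#' description), 8-bit by default on the 0-255 intensity scale.
#'
#' @param dna,rrna,phage numeric matrices of identical dimensions,
#'   intensities >= 0.
#' @param pixel_size micrometres per pixel.
#' @return a `field_image`.
#' @export
field_image <- function(dna, rrna, phage, pixel_size) {
  stopifnot(is.matrix(dna), is.matrix(rrna), is.matrix(phage))
  if (!all(dim(dna) == dim(rrna)) || !all(dim(dna) == dim(phage)))
    stop("channel planes must have identical dimensions")
  if (min(dna, rrna, phage) < 0) stop("intensities must be non-negative")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(dna = dna, rrna = rrna, phage = phage,
                 pixel_size = pixel_size), class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat("field_image:", nrow(x$dna), "x", ncol(x$dna), "px @", x$pixel_size,
      "um/px; channels dna/rrna/phage\n")
  invisible(x)
}

#' Write a field image as a multi-page TIFF
#'
#' Intensities are clipped to `[0, 2^bits - 1]` and quantized. Channel
#' order and pixel size are recorded in a JSON sidecar
#' (`<path>.meta.json`), as baseline TIFF has no standard slot for them.
#'
#' @param field a `field_image`.
#' @param path output file path.
#' @param bits 8 (default, matching 8-bit grayscale acquisition) or 16.
#' @return the path, invisibly.
#' @export
write_field_tiff <- function(field, path, bits = 8) {
  stopifnot(inherits(field, "field_image"), bits %in% c(8, 16))
  top <- 2^bits - 1
  pages <- lapply(field[channel_names], function(m) {
    pmin(pmax(round(m), 0), top) / top
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(list(channels = channel_names,
                            pixel_size = field$pixel_size, bits = bits),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a field image written by [write_field_tiff()]
#'
#' @param path TIFF path (3 grayscale pages, dna/rrna/phage order).
#' @param pixel_size micrometres per pixel; if `NULL`, read from the
#'   sidecar written by [write_field_tiff()].
#' @param bits bit depth used at write time (restores the 0-255 or
#'   0-65535 intensity scale); if `NULL`, from the sidecar.
#' @return a `field_image`.
#' @export
read_field_tiff <- function(path, pixel_size = NULL, bits = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3)
    stop("expected a 3-page TIFF (dna/rrna/phage), got ", length(pages),
         " pages")
  meta_path <- paste0(path, ".meta.json")
  if (is.null(pixel_size) || is.null(bits)) {
    if (!file.exists(meta_path))
      stop("pixel_size/bits not given and no sidecar ", meta_path)
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% meta$pixel_size
    bits <- bits %||% meta$bits
  }
  top <- 2^bits - 1
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]   # tolerate grey-as-RGB
    unclass(p) * top
  })
  field_image(pages[[1]], pages[[2]], pages[[3]], pixel_size)
}

#' Write a ground-truth table as TSV
#'
#' @param truth ground-truth data.frame from [render_field()] or the truth
#'   table from [render_timeseries()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
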