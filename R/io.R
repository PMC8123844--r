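# File formats: two-page 8-bit grayscale TIFF per nucleus (page 1 chromatin,
# page 2 marker), PNG previews/masks, CSV tables.

#' Write / read a two-channel nucleus TIFF
#'
#' Page 1 carries the chromatin channel, page 2 the marker channel, both as
#' 8-bit grayscale.
#'
#' @param image A [nucleus_image()].
#' @param path TIFF path.
#' @return `path` (write) or a [nucleus_image()] (read).
#' @export
write_nucleus_tiff <- function(image, path) {
  tiff::writeTIFF(list(image$chromatin / 255, image$marker / 255),
                  path, bits.per.sample = 8, compression = "none")
  invisible(path)
}

#' @rdname write_nucleus_tiff
#' @export
read_nucleus_tiff <- function(path) {
  if (!file.exists(path)) abort(paste0("no such image file: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2)
    abort(paste0("missing marker channel (need 2 pages): ", path))
  to_m <- function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    matrix(as.integer(round(p * 255)), nrow(p), ncol(p))
  }
  nucleus_image(to_m(pages[[1]]), to_m(pages[[2]]))
}

#' Write a binary mask as PNG
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}
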