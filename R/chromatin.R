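# Chromatin-channel analysis: nucleus / nucleolus segmentation,
# heterochromatin thresholding, and the pixel-count area metrics.

#' Segment the nucleus from the chromatin channel
#'
#' Global automatic threshold (Otsu inter-class-variance split) of the
#' chromatin channel, hole filling, then the largest connected foreground
#' component.
#'
#' @param image A [nucleus_image()].
#' @param min_area Minimum acceptable nucleus area in px.
#' @return Logical nucleus mask.
#' @export
segment_nucleus <- function(image, min_area = 500) {
  chrom <- image$chromatin
  if (length(chrom) == 0) abort("empty image")
  thr <- otsu_threshold(as.vector(chrom))
  fg <- chrom > thr
  if (!any(fg)) abort("no nucleus found: thresholded image is empty")
  fg <- fill_holes(fg)
  lab <- label_components(fg, connectivity = 4)
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_area)
    abort(paste0("no nucleus found: largest component is ",
                 max(sizes), " px (< ", min_area, ")"))
  matrix(lab == which.max(sizes), nrow(chrom), ncol(chrom))
}

#' Segment the nucleolus (chromatin-dark interior body)
#'
#' The nucleolus is the largest dark connected region strictly inside the
#' eroded nucleus: pixels below a percentile of the intra-nucleus chromatin
#' intensities, hole-filled.  An empty mask is a valid result (no nucleolus
#' above the minimum area).
#'
#' @inheritParams segment_nucleus
#' @param nucleus_mask Logical mask from [segment_nucleus()].
#' @param percentile Intensity percentile defining "dark" (default 20th).
#' @param min_area Minimum nucleolus area in px.
#' @param erode_px Erosion of the nucleus before the search, keeping the
#'   candidate region strictly interior.
#' @return Logical nucleolus mask (possibly empty).
#' @export
segment_nucleolus <- function(image, nucleus_mask, percentile = 0.2,
                              min_area = 50, erode_px = 3) {
  stopifnot_mask(nucleus_mask, "nucleus_mask")
  if (!any(nucleus_mask)) abort("`nucleus_mask` is empty")
  chrom <- image$chromatin
  thr <- quantile(chrom[nucleus_mask], percentile, names = FALSE)
  interior <- erode_mask(nucleus_mask, erode_px)
  cand <- interior & chrom < thr
  empty <- matrix(FALSE, nrow(chrom), ncol(chrom))
  if (!any(cand)) return(empty)
  lab <- label_components(cand, connectivity = 4)
  sizes <- tabulate(lab[lab > 0L])
  if (max(sizes) < min_area) return(empty)
  fill_holes(matrix(lab == which.max(sizes), nrow(chrom), ncol(chrom))) &
    nucleus_mask
}

#' Threshold heterochromatin inside the nucleus
#'
#' Bright condensed-chromatin pixels inside the nucleus: intensity at or
#' above an automatic bimodal (Otsu) split of the intra-nucleus intensities,
#' or a fixed user threshold.  Speckles below `min_speck` px are removed.
#' `exclude_mask` (typically the segmented nucleolus, whose dark mode would
#' otherwise attract the split at low heterochromatin content) is excluded
#' from threshold *estimation* only; the returned mask is still evaluated on
#' every intra-nucleus pixel.
#'
#' @inheritParams segment_nucleolus
#' @param threshold Optional fixed intensity threshold (overrides Otsu).
#' @param exclude_mask Optional mask excluded from threshold estimation.
#' @param min_speck Minimum component size kept, in px.
#' @return Logical heterochromatin mask with attribute `threshold`.
#' @export
threshold_heterochromatin <- function(image, nucleus_mask, threshold = NULL,
                                      exclude_mask = NULL, min_speck = 4) {
  stopifnot_mask(nucleus_mask, "nucleus_mask")
  if (!any(nucleus_mask)) abort("`nucleus_mask` is empty")
  chrom <- image$chromatin
  est_region <- nucleus_mask
  if (!is.null(exclude_mask)) est_region <- est_region & !exclude_mask
  vals <- chrom[est_region]
  empty <- matrix(FALSE, nrow(chrom), ncol(chrom))
  if (is.null(threshold)) {
    if (diff(range(vals)) == 0) {
      warn("degenerate intra-nucleus intensity histogram: empty HC mask")
      out <- empty
      attr(out, "threshold") <- NA_real_
      return(out)
    }
    threshold <- otsu_threshold(vals)
  }
  mask <- nucleus_mask & chrom >= threshold
  mask <- remove_specks(mask, min_speck)
  attr(mask, "threshold") <- threshold
  mask
}

#' Pixel-count area metrics of a segmented nucleus
#'
#' @param masks List with logical `nucleus`, `nucleolus`, `hc` masks of equal
#'   shape (e.g. segmentation output, or planted ground-truth masks).
#' @return One-row tibble: `nucleus_area_px`, `nucleolus_area_px`,
#'   `hc_area_px`, `hc_percent` (= 100 * hc / nucleus area).
#' @export
chromatin_metrics <- function(masks) {
  stopifnot_mask(masks$nucleus, "nucleus")
  if (!identical(dim(masks$nucleus), dim(masks$hc)) ||
      !identical(dim(masks$nucleus), dim(masks$nucleolus)))
    abort("masks must share one shape")
  n_area <- mask_area(masks$nucleus)
  if (n_area == 0) abort("zero nucleus area")
  tibble(
    nucleus_area_px = n_area,
    nucleolus_area_px = mask_area(masks$nucleolus),
    hc_area_px = mask_area(masks$hc),
    hc_percent = 100 * mask_area(masks$hc) / n_area)
}
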