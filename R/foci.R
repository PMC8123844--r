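# Marker-channel focus detection and per-nucleus focus metrics.

#' Detect marker foci inside the nucleus
#'
#' The marker channel is restricted to the nucleus; the detection threshold
#' is the intra-nucleus background floor (median) plus the larger of
#' `k * MAD` and `min_rise` (the fixed rise guards the noiseless case, where
#' the robust spread collapses to zero).  8-connected components with area
#' >= `min_focus_px` become focus records.  An empty set is a valid result
#' (unlabeled nucleus).
#'
#' @param image A [nucleus_image()].
#' @param nucleus_mask Logical mask from [segment_nucleus()].
#' @param nucleolus_mask Optional nucleolus mask for localization features.
#' @param k Robust-spread multiplier (default 3).
#' @param min_rise Minimum rise above the floor, intensity units.
#' @param min_focus_px Minimum component area in px.
#' @param threshold Optional fixed threshold overriding the automatic rule.
#' @return A `foci_set`: list with `foci` tibble (`label`, `area_px`,
#'   `mean_intensity`, `max_intensity`, `row`, `col`, `inside_nucleolus`,
#'   `boundary_distance_px`), summary fields (`count`, `total_area_px`,
#'   `mean_area_px`, `area_sd`, `coverage_percent`, `labeled`), the binary
#'   `mask` and the `threshold` used.
#' @export
detect_foci <- function(image, nucleus_mask, nucleolus_mask = NULL,
                        k = 3, min_rise = 40, min_focus_px = 3,
                        threshold = NULL) {
  stopifnot_mask(nucleus_mask, "nucleus_mask")
  if (!any(nucleus_mask)) abort("`nucleus_mask` is empty")
  marker <- image$marker
  vals <- marker[nucleus_mask]
  if (is.null(threshold)) {
    floor_ <- median(vals)
    spread <- mad(vals)
    threshold <- floor_ + max(k * spread, min_rise)
  }
  mask <- nucleus_mask & marker > threshold
  mask <- remove_specks(mask, min_focus_px)
  lab <- label_components(mask, connectivity = 8)
  comp <- component_table(lab)
  if (nrow(comp) > 0) {
    idx <- which(lab > 0L)
    ints <- tibble(label = lab[idx], v = marker[idx]) %>%
      group_by(.data$label) %>%
      summarise(mean_intensity = mean(.data$v),
                max_intensity = max(.data$v), .groups = "drop")
    comp <- left_join(comp, ints, by = "label")
    if (!is.null(nucleolus_mask) && any(nucleolus_mask)) {
      pr <- pmin(pmax(round(comp$row), 1), nrow(marker))
      pc <- pmin(pmax(round(comp$col), 1), ncol(marker))
      comp$inside_nucleolus <- nucleolus_mask[cbind(pr, pc)]
      d_out <- distance_to_mask(nucleolus_mask)
      d_in <- distance_to_mask(!nucleolus_mask)
      signed <- d_out - d_in  # negative inside the nucleolus
      comp$boundary_distance_px <- signed[cbind(pr, pc)]
    } else {
      comp$inside_nucleolus <- FALSE
      comp$boundary_distance_px <- NA_real_
    }
  } else {
    comp <- tibble(label = integer(), area_px = integer(), row = double(),
                   col = double(), mean_intensity = double(),
                   max_intensity = double(), inside_nucleolus = logical(),
                   boundary_distance_px = double())
  }
  total <- sum(comp$area_px)
  structure(list(
    foci = select(comp, "label", "area_px", "mean_intensity",
                  "max_intensity", "row", "col", "inside_nucleolus",
                  "boundary_distance_px"),
    count = nrow(comp),
    total_area_px = total,
    mean_area_px = if (nrow(comp) > 0) mean(comp$area_px) else 0,
    area_sd = if (nrow(comp) > 1) sd(comp$area_px) else 0,
    coverage_percent = 100 * total / mask_area(nucleus_mask),
    labeled = nrow(comp) > 0,
    mask = mask,
    threshold = threshold), class = "foci_set")
}

#' @export
print.foci_set <- function(x, ...) {
  cat("<foci_set>", x$count, "foci, total", x$total_area_px,
      "px,", sprintf("%.2f%%", x$coverage_percent), "coverage\n")
  invisible(x)
}

#' @export
tidy.foci_set <- function(x, ...) x$foci

#' @export
glance.foci_set <- function(x, ...) {
  tibble(count = x$count, total_area_px = x$total_area_px,
         mean_area_px = x$mean_area_px, area_sd = x$area_sd,
         coverage_percent = x$coverage_percent, labeled = x$labeled,
         threshold = x$threshold)
}

#' Labeling index of a nucleus population
#'
#' Percentage of nuclei showing any detectable marker foci.
#'
#' @param x A list of `foci_set` objects, a logical vector of labeled flags,
#'   or a data frame with a `labeled` column.
#' @return Percentage in \[0, 100\].
#' @export
labeling_index <- function(x) {
  labeled <- if (is.data.frame(x)) {
    x$labeled
  } else if (is.list(x)) {
    map_lgl(x, function(f) isTRUE(f$labeled))
  } else {
    as.logical(x)
  }
  if (length(labeled) == 0) abort("empty population")
  100 * mean(labeled)
}

#' Clustering summary of a focus set
#'
#' A focus is a "large cluster" when its area reaches `cluster_factor` times
#' the population's median singleton area; when no population median is
#' supplied the absolute fallback `fallback_px` is used.
#'
#' @param fociset A `foci_set`.
#' @param median_singleton_area Optional population median singleton area.
#' @param cluster_factor Multiplier on the median singleton area.
#' @param fallback_px Absolute size threshold when no median is available.
#' @return One-row tibble: `large_cluster_count`,
#'   `large_cluster_area_fraction`, `size_threshold_px`.
#' @export
cluster_stats <- function(fociset, median_singleton_area = NULL,
                          cluster_factor = 5, fallback_px = 50) {
  thr <- if (!is.null(median_singleton_area))
    cluster_factor * median_singleton_area else fallback_px
  areas <- fociset$foci$area_px
  large <- areas >= thr
  tibble(
    large_cluster_count = sum(large),
    large_cluster_area_fraction =
      if (length(areas) > 0) sum(areas[large]) / sum(areas) else 0,
    size_threshold_px = thr)
}

#' Intensity profile along a polyline
#'
#' Marker intensities sampled at unit spacing along the polyline using
#' nearest-pixel lookup, as used for line plots across the nucleolus border.
#'
#' @param image A [nucleus_image()].
#' @param polyline Two-column matrix of (row, col) vertices.
#' @param channel `"marker"` (default) or `"chromatin"`.
#' @return Numeric vector of intensities in \[0, 255\].
#' @export
line_profile <- function(image, polyline, channel = c("marker",
                                                      "chromatin")) {
  channel <- match.arg(channel)
  img <- image[[channel]]
  polyline <- matrix(as.numeric(polyline), ncol = 2)
  if (any(polyline[, 1] < 1 | polyline[, 1] > nrow(img) |
            polyline[, 2] < 1 | polyline[, 2] > ncol(img)))
    abort("polyline vertex outside image bounds")
  if (nrow(polyline) == 1) {
    return(img[round(polyline[1, 1]), round(polyline[1, 2])])
  }
  pts <- list(polyline[1, ])
  for (i in seq_len(nrow(polyline) - 1)) {
    a <- polyline[i, ]; b <- polyline[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    ts <- seq_len(ceiling(len)) / ceiling(len)
    seg <- lapply(ts, function(t) a + t * (b - a))
    pts <- c(pts, seg)
  }
  pm <- do.call(rbind, pts)
  img[cbind(round(pm[, 1]), round(pm[, 2]))]
}

#' Flame false-color palette
#'
#' Monotone-luminance map from black through blue, red and orange to yellow
#' and white, mirroring the heatmap rendering of marker activity.
#'
#' @param n Number of colors.
#' @return Character vector of hex colors.
#' @export
flame_palette <- function(n = 256) {
  grDevices::colorRampPalette(
    c("black", "blue", "red", "orange", "yellow", "white"))(n)
}

#' Export a false-color marker heatmap
#'
#' Writes a PNG of the marker intensities inside the nucleus using the flame
#' palette; masked-out pixels render black.  Pure visualization: no analysis
#' output depends on this file.
#'
#' @inheritParams detect_foci
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
heatmap_export <- function(image, nucleus_mask, path) {
  stopifnot_mask(nucleus_mask, "nucleus_mask")
  pal <- flame_palette(256)
  rgb <- grDevices::col2rgb(pal) / 255
  marker <- image$marker
  idx <- pmin(pmax(as.integer(marker), 0L), 255L) + 1L
  arr <- array(0, c(nrow(marker), ncol(marker), 3))
  for (ch in 1:3) {
    plane <- matrix(rgb[ch, idx], nrow(marker), ncol(marker))
    plane[!nucleus_mask] <- 0
    arr[, , ch] <- plane
  }
  png::writePNG(arr, path)
  invisible(path)
}
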