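# Localization features and the rule-based five-profile classifier.

annulus_width <- function(nucleolus_mask) {
  max(3, 0.15 * sqrt(mask_area(nucleolus_mask) / pi))
}

#' Perinucleolar annulus mask
#'
#' Ring of pixels just outside the nucleolus, of width
#' `max(3 px, 0.15 * equivalent nucleolus radius)`, clipped to the nucleus.
#' This is the zone where the ring profile (`T2A`) plants its high-intensity
#' foci.
#'
#' @param nucleolus_mask Logical nucleolus mask (must be non-empty).
#' @param nucleus_mask Logical nucleus mask.
#' @return Logical annulus mask with attribute `width_px`.
#' @export
perinucleolar_annulus <- function(nucleolus_mask, nucleus_mask) {
  stopifnot_mask(nucleolus_mask, "nucleolus_mask")
  if (!any(nucleolus_mask))
    abort("empty nucleolus mask: annulus undefined")
  w <- annulus_width(nucleolus_mask)
  d <- distance_to_mask(nucleolus_mask)
  out <- d > 0 & d <= w & nucleus_mask & !nucleolus_mask
  attr(out, "width_px") <- w
  out
}

#' Localization features of a labeled nucleus
#'
#' Feature vector feeding the profile classifier: fraction of foci inside
#' the nucleolus; ring score (fraction of 12 equal angular sectors of the
#' perinucleolar annulus, centered at the nucleolus centroid, containing at
#' least one focus centroid); ring focus count and the intensity ratio of
#' annulus foci to all foci; large-cluster area fraction (from
#' [cluster_stats()]); and the marker brightness of the nucleolus relative
#' to the non-focus nucleoplasm (the light/dark nucleolus appearance).
#' Ring and brightness features are `NA` when no nucleolus is available.
#'
#' @param fociset A non-empty `foci_set` from [detect_foci()].
#' @param masks List with `nucleus` and `nucleolus` masks (nucleolus may be
#'   empty).
#' @param image A [nucleus_image()].
#' @param n_sectors Number of angular sectors for the ring score.
#' @inheritParams cluster_stats
#' @return One-row tibble of features.
#' @export
compute_profile_features <- function(fociset, masks, image, n_sectors = 12,
                                     median_singleton_area = NULL,
                                     cluster_factor = 5, fallback_px = 50) {
  if (fociset$count == 0)
    abort("empty foci set: the nucleus is UNLABELED, no features to compute")
  foci <- fociset$foci
  cs <- cluster_stats(fociset, median_singleton_area, cluster_factor,
                      fallback_px)
  has_no <- any(masks$nucleolus)
  if (has_no) {
    ann <- perinucleolar_annulus(masks$nucleolus, masks$nucleus)
    ct <- component_table(label_components(masks$nucleolus, 4))
    center <- c(ct$row[which.max(ct$area_px)], ct$col[which.max(ct$area_px)])
    pr <- pmin(pmax(round(foci$row), 1), nrow(ann))
    pc <- pmin(pmax(round(foci$col), 1), ncol(ann))
    in_ann <- ann[cbind(pr, pc)]
    ring_focus_count <- sum(in_ann)
    if (ring_focus_count > 0) {
      ang <- atan2(foci$col[in_ann] - center[2], foci$row[in_ann] - center[1])
      sector <- floor((ang + pi) / (2 * pi) * n_sectors) %% n_sectors
      ring_score <- length(unique(sector)) / n_sectors
      ring_intensity_ratio <- mean(foci$mean_intensity[in_ann]) /
        mean(foci$mean_intensity)
    } else {
      ring_score <- 0
      ring_intensity_ratio <- 0
    }
    nonfocus_np <- masks$nucleus & !masks$nucleolus & !fociset$mask
    nucleolus_brightness_ratio <-
      mean(image$marker[masks$nucleolus]) / mean(image$marker[nonfocus_np])
    nucleolar_focus_fraction <- mean(foci$inside_nucleolus)
  } else {
    ring_score <- NA_real_
    ring_focus_count <- NA_integer_
    ring_intensity_ratio <- NA_real_
    nucleolus_brightness_ratio <- NA_real_
    nucleolar_focus_fraction <- 0
  }
  tibble(
    nucleolar_focus_fraction = nucleolar_focus_fraction,
    ring_score = ring_score,
    ring_focus_count = ring_focus_count,
    ring_intensity_ratio = ring_intensity_ratio,
    large_cluster_area_fraction = cs$large_cluster_area_fraction,
    nucleolus_brightness_ratio = nucleolus_brightness_ratio,
    nucleolus_missing = !has_no)
}

#' Default classifier thresholds
#'
#' Numeric operationalizations of the five qualitative profile criteria;
#' every value is configurable.  `t3_cluster_fraction` encodes "large
#' clusters covering the entire nucleus"; `ring_score_min`,
#' `ring_count_min` and `ring_ratio_min` encode "highly active foci forming
#' a ring on the nucleolus perimeter"; `t1_nucleolar_fraction` encodes
#' "foci located only within the nucleolus"; `t2_nucleolar_max` and
#' `light_threshold` encode "foci evenly outside the nucleolus, nucleolus
#' not labeled".
#'
#' @return Named list of thresholds.
#' @export
classifier_thresholds <- function() {
  list(t3_cluster_fraction = 0.5,
       ring_score_min = 0.5,
       ring_count_min = 4,
       ring_ratio_min = 1.0,
       t1_nucleolar_fraction = 0.9,
       t2_nucleolar_max = 0.05,
       light_threshold = 1.2)
}

#' Classify a feature vector into one of the five profiles
#'
#' Ordered decision rule: T3 (large-cluster area fraction), then T2A (ring
#' score, count and intensity ratio), then T1 (nucleolar focus fraction),
#' then T2 (no nucleolar foci and a dark nucleolus), else T2B.  Precedence
#' puts the two most distinctive morphologies (merged clusters, ring) first.
#' When the nucleolus could not be segmented the ring/nucleolar rules are
#' skipped and the nucleus is classified among T3/T2 with a flag.
#'
#' @param features One-row tibble from [compute_profile_features()].
#' @param thresholds Named list as from [classifier_thresholds()].
#' @return One-row tibble: `type`, `decision_path`, `nucleolus_missing`.
#' @export
classify_profile <- function(features, thresholds = classifier_thresholds()) {
  f <- features
  th <- modifyList(classifier_thresholds(), thresholds)
  path <- character()
  step <- function(txt) path <<- c(path, txt)
  type <- NULL
  if (f$large_cluster_area_fraction >= th$t3_cluster_fraction) {
    step(sprintf("T3: cluster_fraction %.2f >= %.2f",
                 f$large_cluster_area_fraction, th$t3_cluster_fraction))
    type <- "T3"
  } else {
    step(sprintf("not T3: cluster_fraction %.2f < %.2f",
                 f$large_cluster_area_fraction, th$t3_cluster_fraction))
    if (isTRUE(f$nucleolus_missing)) {
      step("nucleolus missing: restricted to {T2, T2B, T3}")
      type <- "T2"
    } else if (!is.na(f$ring_score) &&
               f$ring_score >= th$ring_score_min &&
               f$ring_focus_count >= th$ring_count_min &&
               f$ring_intensity_ratio >= th$ring_ratio_min) {
      step(sprintf("T2A: ring_score %.2f, ring foci %d, ratio %.2f",
                   f$ring_score, f$ring_focus_count, f$ring_intensity_ratio))
      type <- "T2A"
    } else if (f$nucleolar_focus_fraction >= th$t1_nucleolar_fraction) {
      step(sprintf("T1: nucleolar_fraction %.2f >= %.2f",
                   f$nucleolar_focus_fraction, th$t1_nucleolar_fraction))
      type <- "T1"
    } else if (f$nucleolar_focus_fraction <= th$t2_nucleolar_max &&
               f$nucleolus_brightness_ratio < th$light_threshold) {
      step(sprintf("T2: nucleolar_fraction %.2f <= %.2f, brightness %.2f < %.2f",
                   f$nucleolar_focus_fraction, th$t2_nucleolar_max,
                   f$nucleolus_brightness_ratio, th$light_threshold))
      type <- "T2"
    } else {
      step("T2B: default (foci across both compartments or light nucleolus)")
      type <- "T2B"
    }
  }
  tibble(type = type, decision_path = paste(path, collapse = " | "),
         nucleolus_missing = isTRUE(f$nucleolus_missing))
}

#' Profile-type distribution per condition
#'
#' Percentages per type over *labeled* nuclei of each condition; the
#' unlabeled share is reported separately alongside the labeling index.
#' Conditions without any labeled nucleus get `NA` percentages and a flag.
#'
#' @param classifications Tibble with columns `condition` and `type`
#'   (`"UNLABELED"` rows allowed).
#' @return Tibble: `condition`, `type`, `n`, `percent` (over labeled
#'   nuclei), `percent_all` (over all nuclei), `labeling_index_percent`,
#'   `undefined` flag.
#' @export
type_distribution <- function(classifications) {
  if (nrow(classifications) == 0) abort("no classifications supplied")
  totals <- classifications %>%
    group_by(.data$condition) %>%
    summarise(n_total = n(),
              n_labeled = sum(.data$type != "UNLABELED"),
              .groups = "drop")
  counts <- classifications %>%
    filter(.data$type != "UNLABELED") %>%
    count(.data$condition, .data$type)
  left_join(totals, counts, by = "condition") %>%
    mutate(labeling_index_percent = 100 * .data$n_labeled / .data$n_total,
           undefined = .data$n_labeled == 0,
           percent = ifelse(.data$n_labeled > 0,
                            100 * .data$n / .data$n_labeled, NA_real_),
           percent_all = 100 * .data$n / .data$n_total) %>%
    select("condition", "type", "n", "percent", "percent_all",
           "labeling_index_percent", "undefined")
}
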