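# Specification objects for the synthetic nucleus generator: the study
# conditions (control, hydroxyurea, hydroxyurea + caffeine) and the five
# marker-activity profile types.

#' Profile type and condition vocabularies
#'
#' The five nuclear marker-activity profiles: `T1` (foci only inside the
#' nucleolus), `T2` (small foci only outside the nucleolus), `T2A` (as `T2`
#' plus a perinucleolar ring of high-intensity foci), `T2B` (foci over the
#' whole nucleus including the nucleolus) and `T3` (large merged clusters).
#' Conditions are `CONTROL`, `HU` (hydroxyurea replication arrest) and `PCC`
#' (hydroxyurea + caffeine checkpoint override).
#'
#' @return Character vector of levels.
#' @export
profile_types <- function() c("T1", "T2", "T2A", "T2B", "T3")

#' @rdname profile_types
#' @export
conditions <- function() c("CONTROL", "HU", "PCC")

# Per-type generator defaults (control condition).  Counts and sizes are free
# parameters of the emulation; chosen to reproduce the qualitative morphology
# of each profile at the default 256 x 256 px frame.
type_defaults <- function(profile_type) {
  switch(profile_type,
    T1 = list(focus_count = 5, focus_radius_px = 3, focus_intensity = 150,
              nucleolus_appearance = "LIGHT"),
    T2 = list(focus_count = 25, focus_radius_px = 2.5, focus_intensity = 180,
              nucleolus_appearance = "DARK"),
    T2A = list(focus_count = 30, focus_radius_px = 2.5, focus_intensity = 180,
               ring_focus_count = 10, nucleolus_appearance = "DARK"),
    T2B = list(focus_count = 25, focus_radius_px = 2.5, focus_intensity = 140,
               nucleolus_appearance = "DARK"),
    T3 = list(focus_count = 29, focus_radius_px = 3, focus_intensity = 200,
              cluster_count = 3, cluster_span_px = 25,
              nucleolus_appearance = "DARK"),
    abort(paste0("unknown profile_type: ", profile_type))
  )
}

# Treatment effect multipliers.  The source observations give direction only
# (fewer, dimmer foci under HU; partial restoration with smaller, separated
# clusters under PCC); the magnitudes are configurable defaults.
condition_effects <- function(condition) {
  switch(condition,
    CONTROL = list(count_mult = 1, intensity_mult = 1, cluster_tight = TRUE,
                   linear_formation_count = 0L),
    HU = list(count_mult = 0.4, intensity_mult = 0.6, cluster_tight = TRUE,
              linear_formation_count = 1L),
    PCC = list(count_mult = 0.6, intensity_mult = 0.8, cluster_tight = FALSE,
               linear_formation_count = 1L),
    abort(paste0("unknown condition: ", condition))
  )
}

#' Default labeling fraction per condition
#'
#' Fraction of nuclei carrying any detectable marker foci (the labeling
#' index / 100) used by the population generator: 0.895 for control and
#' 0.352 for hydroxyurea are the measured series values; the combined
#' hydroxyurea + caffeine series value is not reported and defaults to 0.60
#' (between the other two, matching the observed partial restoration).
#'
#' @param condition One of `conditions()`.
#' @return Fraction in \[0, 1\].
#' @export
default_labeling_fraction <- function(condition) {
  condition <- match.arg(condition, conditions())
  c(CONTROL = 0.895, HU = 0.352, PCC = 0.60)[[condition]]
}

#' Reference phase fractions per condition
#'
#' G1/S/G2M fractions for each treatment series, built from the measured
#' flow-cytometry S-phase and M-phase indices (S = 26.17/41.06/38.51% and
#' M = 2.4--11.25% for control/HU/PCC).  DNA content cannot separate M from
#' G2, so the M index is folded into the G2M component and G1 is the
#' remainder.
#'
#' @inheritParams default_labeling_fraction
#' @return Named numeric vector `c(g1, s, g2m)` summing to 1.
#' @export
condition_phase_fractions <- function(condition) {
  condition <- match.arg(condition, conditions())
  sm <- switch(condition,
    CONTROL = c(s = 26.17, m = 8.18),
    HU = c(s = 41.06, m = 2.4),
    PCC = c(s = 38.51, m = 11.25))
  c(g1 = (100 - sm[["s"]] - sm[["m"]]) / 100,
    s = sm[["s"]] / 100, g2m = sm[["m"]] / 100)
}

#' Build a synthetic nucleus specification
#'
#' Collects every tunable of a single simulated nucleus: geometry (nucleus /
#' nucleolus semi-axes), heterochromatin content, marker foci (count, size,
#' peak intensity and type-specific placement) and imaging parameters
#' (background level, Gaussian noise).  Per-type defaults are filled in from
#' `profile_type`; treatment multipliers are applied later by [plant_foci()].
#'
#' @param profile_type One of [profile_types()].
#' @param condition One of [conditions()].
#' @param nucleolus_appearance `"DARK"` or `"LIGHT"`: marker-channel
#'   fluorescence of the nucleolus body (a marker property, independent of
#'   the chromatin-channel darkness used for segmentation).
#' @param nucleus_axes,nucleolus_axes Semi-axes in px (length-2 numeric).
#' @param hc_blob_count Number of heterochromatin blob seeds.
#' @param hc_target_fraction Heterochromatin area as a fraction of nucleus
#'   area, in \[0, 0.6\].
#' @param focus_count Mean number of foci (before treatment multipliers).
#' @param focus_radius_px Mean focus radius in px.
#' @param focus_intensity Mean peak intensity in \[0, 255\].
#' @param ring_focus_count Perinucleolar ring foci (T2A only).
#' @param cluster_count,cluster_span_px Cluster seeds and merged-component
#'   span (T3 only).
#' @param linear_formation_count Number of collinear 2--5 focus formations.
#' @param background_level Autofluorescence floor in \[0, 255\].
#' @param noise_sd Gaussian read-noise standard deviation (intensity units).
#' @param nucleoplasm_level,hc_level,nucleolus_level Chromatin-channel
#'   rendering intensities.
#' @param light_nucleolus_level Diffuse marker elevation added inside a
#'   `"LIGHT"` nucleolus.
#' @param dim Image height and width in px.
#' @return A `nucleus_spec` list.
#' @export
nucleus_spec <- function(profile_type = "T2",
                         condition = "CONTROL",
                         nucleolus_appearance = NULL,
                         nucleus_axes = c(55, 40),
                         nucleolus_axes = c(18, 14),
                         hc_blob_count = 12L,
                         hc_target_fraction = 0.20,
                         focus_count = NULL,
                         focus_radius_px = NULL,
                         focus_intensity = NULL,
                         ring_focus_count = NULL,
                         cluster_count = NULL,
                         cluster_span_px = NULL,
                         linear_formation_count = NULL,
                         background_level = 10,
                         noise_sd = 5,
                         nucleoplasm_level = 120,
                         hc_level = 200,
                         nucleolus_level = 70,
                         light_nucleolus_level = 30,
                         dim = c(256L, 256L)) {
  profile_type <- match.arg(profile_type, profile_types())
  condition <- match.arg(condition, conditions())
  defaults <- type_defaults(profile_type)
  eff <- condition_effects(condition)
  spec <- list(
    profile_type = profile_type,
    condition = condition,
    nucleolus_appearance = nucleolus_appearance %||%
      defaults$nucleolus_appearance,
    nucleus_axes = as.numeric(nucleus_axes),
    nucleolus_axes = as.numeric(nucleolus_axes),
    hc_blob_count = as.integer(hc_blob_count),
    hc_target_fraction = hc_target_fraction,
    focus_count = focus_count %||% defaults$focus_count,
    focus_radius_px = focus_radius_px %||% defaults$focus_radius_px,
    focus_intensity = focus_intensity %||% defaults$focus_intensity,
    ring_focus_count = ring_focus_count %||% defaults$ring_focus_count %||% 0L,
    cluster_count = cluster_count %||% defaults$cluster_count %||% 0L,
    cluster_span_px = cluster_span_px %||% defaults$cluster_span_px %||% 0,
    linear_formation_count = linear_formation_count %||%
      eff$linear_formation_count,
    background_level = background_level,
    noise_sd = noise_sd,
    nucleoplasm_level = nucleoplasm_level,
    hc_level = hc_level,
    nucleolus_level = nucleolus_level,
    light_nucleolus_level = light_nucleolus_level,
    dim = as.integer(dim)
  )
  class(spec) <- "nucleus_spec"
  validate_nucleus_spec(spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_nucleus_spec <- function(spec) {
  if (length(spec$nucleus_axes) != 2 || any(spec$nucleus_axes <= 0))
    abort("`nucleus_axes` must be two positive lengths")
  if (length(spec$nucleolus_axes) != 2 || any(spec$nucleolus_axes <= 0))
    abort("`nucleolus_axes` must be two positive lengths")
  if (any(spec$nucleolus_axes >= spec$nucleus_axes))
    abort("nucleolus axes must be strictly smaller than nucleus axes")
  if (spec$hc_target_fraction < 0 || spec$hc_target_fraction > 0.6)
    abort("`hc_target_fraction` must lie in [0, 0.6]")
  ints <- c(spec$background_level, spec$focus_intensity,
            spec$nucleoplasm_level, spec$hc_level, spec$nucleolus_level)
  if (any(ints < 0 | ints > 255))
    abort("all intensity levels must lie in [0, 255]")
  if (spec$focus_count < 0) abort("`focus_count` must be >= 0")
  if (spec$profile_type == "T2A" &&
      spec$focus_count < spec$ring_focus_count)
    abort("`focus_count` must be >= `ring_focus_count` for T2A")
  if (!spec$nucleolus_appearance %in% c("DARK", "LIGHT"))
    abort('`nucleolus_appearance` must be "DARK" or "LIGHT"')
  if (spec$noise_sd < 0) abort("`noise_sd` must be >= 0")
  spec
}

#' @export
print.nucleus_spec <- function(x, ...) {
  cat("<nucleus_spec>", x$profile_type, "/", x$condition,
      "/", x$nucleolus_appearance, "\n")
  cat("  nucleus", paste(x$nucleus_axes, collapse = "x"),
      "px; nucleolus", paste(x$nucleolus_axes, collapse = "x"), "px\n")
  cat("  HC target", x$hc_target_fraction, "in", x$hc_blob_count, "blobs;",
      x$focus_count, "foci r =", x$focus_radius_px,
      "peak =", x$focus_intensity, "\n")
  invisible(x)
}
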