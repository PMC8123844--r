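# Rendering stages of the synthetic generator: chromatin channel, focus
# planting by profile type, and the marker channel.

#' Two-channel nucleus image container
#'
#' @param chromatin,marker Integer matrices in \[0, 255\] of equal shape
#'   (chromatin = DAPI-like density channel, marker = immunofluorescence
#'   channel).
#' @param pixel_size_um Optional pixel size (metadata only; all computation
#'   is in px).
#' @return A `nucleus_image` object.
#' @export
nucleus_image <- function(chromatin, marker, pixel_size_um = 0.1) {
  if (!is.matrix(chromatin) || !is.matrix(marker) ||
      !identical(dim(chromatin), dim(marker)))
    abort("`chromatin` and `marker` must be matrices of identical shape")
  rng <- range(chromatin, marker)
  if (rng[1] < 0 || rng[2] > 255)
    abort("intensities must lie in [0, 255]")
  structure(list(chromatin = chromatin, marker = marker,
                 pixel_size_um = pixel_size_um),
            class = "nucleus_image")
}

#' @export
print.nucleus_image <- function(x, ...) {
  cat("<nucleus_image>", nrow(x$chromatin), "x", ncol(x$chromatin),
      "px, 2 channels (chromatin, marker)\n")
  invisible(x)
}

#' Render the chromatin (DAPI-like) channel
#'
#' Background at `background_level`, nucleoplasm at mid intensity,
#' heterochromatin blobs bright, and the nucleolus darker than the
#' nucleoplasm (DAPI-dark body).  Gaussian read noise is added, and the
#' result is clipped to the 8-bit range.
#'
#' @param masks Output of [make_geometry()].
#' @param spec A [nucleus_spec()].
#' @param seed Integer seed for the noise stream.
#' @return Integer matrix in \[0, 255\].
#' @export
render_chromatin_channel <- function(masks, spec, seed = 1L) {
  stopifnot_mask(masks$nucleus, "nucleus")
  if (!any(masks$nucleus))
    abort("empty nucleus mask: nothing to render")
  img <- matrix(spec$background_level, nrow(masks$nucleus),
                ncol(masks$nucleus))
  img[masks$nucleus] <- spec$nucleoplasm_level
  img[masks$nucleolus] <- spec$nucleolus_level
  img[masks$hc] <- spec$hc_level
  withr::with_seed(seed, {
    if (spec$noise_sd > 0)
      img <- img + rnorm(length(img), 0, spec$noise_sd)
  })
  as_uint8(img)
}

# Sample n points (with sub-pixel jitter) from a mask, keeping a minimum
# pairwise separation; the separation is relaxed geometrically if the mask is
# too crowded, so the requested count is always delivered.
sample_points_in_mask <- function(mask, n, min_sep) {
  idx <- which(mask)
  if (length(idx) == 0L || n <= 0)
    return(matrix(numeric(0), ncol = 2))
  nr <- nrow(mask)
  pts <- matrix(NA_real_, n, 2)
  got <- 0L
  sep <- min_sep
  tries <- 0L
  while (got < n) {
    cand <- idx[sample.int(length(idx), 1L)]
    pr <- ((cand - 1L) %% nr) + 1L + runif(1, -0.5, 0.5)
    pc <- ((cand - 1L) %/% nr) + 1L + runif(1, -0.5, 0.5)
    ok <- got == 0L ||
      all((pts[seq_len(got), 1] - pr)^2 + (pts[seq_len(got), 2] - pc)^2 >=
            sep^2)
    if (ok) {
      got <- got + 1L
      pts[got, ] <- c(pr, pc)
      tries <- 0L
    } else {
      tries <- tries + 1L
      if (tries > 200L) {
        sep <- sep * 0.8
        tries <- 0L
      }
    }
  }
  pts
}

focus_row <- function(pts, radius, peak, role, cluster_id = NA_integer_) {
  if (nrow(pts) == 0L)
    return(tibble(row = double(), col = double(), radius_px = double(),
                  peak = double(), role = character(),
                  cluster_id = integer()))
  tibble(row = pts[, 1], col = pts[, 2],
         radius_px = radius, peak = peak, role = role,
         cluster_id = as.integer(cluster_id))
}

draw_radii <- function(n, mean_r) pmax(1.5, rnorm(n, mean_r, 0.15 * mean_r))

draw_peaks <- function(n, mean_i) clip01(rnorm(n, mean_i, 0.1 * mean_i),
                                         30, 255)

#' Plant marker foci according to the profile type
#'
#' Placement rules encode the five activity profiles: `T1` inside the
#' nucleolus only; `T2` in the nucleoplasm only; `T2A` as `T2` plus
#' `ring_focus_count` brighter foci on the perinucleolar border spanning at
#' least 180 degrees; `T2B` over both compartments (at least 10% of foci in
#' the nucleolus so the compartment is genuinely occupied); `T3` chains of
#' overlapping foci around `cluster_count` seeds (merging into components of
#' span `cluster_span_px`) plus a minority of singletons.  Treatment effects
#' scale count and intensity (`HU` x0.4 / x0.6, `PCC` x0.6 / x0.8) and `PCC`
#' widens intra-cluster spacing so singular foci stay distinguishable.
#' Linear formations add 2--5 collinear, slightly clustered foci.
#'
#' @inheritParams render_chromatin_channel
#' @return Tibble with one row per planted focus (`row`, `col`, `radius_px`,
#'   `peak`, `role`, `cluster_id`, `in_nucleolus`); attribute
#'   `degenerate_ring` flags a T2A ring with fewer than 4 foci.
#' @export
plant_foci <- function(masks, spec, seed = 1L) {
  withr::with_seed(seed, plant_foci_impl(masks, spec))
}

plant_foci_impl <- function(masks, spec) {
  eff <- condition_effects(spec$condition)
  empty <- focus_row(matrix(numeric(0), ncol = 2), double(), double(),
                     character())
  empty$in_nucleolus <- logical(0)
  attr(empty, "degenerate_ring") <- FALSE
  if (spec$focus_count == 0) return(empty)

  n_eff <- max(1L, round(spec$focus_count * eff$count_mult))
  intensity <- spec$focus_intensity * eff$intensity_mult
  rad <- spec$focus_radius_px
  margin <- ceiling(rad) + 2L
  nucleoplasm <- erode_mask(masks$nucleus, margin) &
    !dilate_mask(masks$nucleolus, 2L)
  inner_no <- erode_mask(masks$nucleolus, ceiling(rad) + 1L)
  if (!any(inner_no)) inner_no <- masks$nucleolus
  degenerate_ring <- FALSE

  foci <- switch(spec$profile_type,
    T1 = {
      pts <- sample_points_in_mask(inner_no, n_eff, 3 * rad)
      focus_row(pts, draw_radii(n_eff, rad), draw_peaks(n_eff, intensity),
                "single")
    },
    T2 = {
      pts <- sample_points_in_mask(nucleoplasm, n_eff, 3 * rad)
      focus_row(pts, draw_radii(n_eff, rad), draw_peaks(n_eff, intensity),
                "single")
    },
    T2A = {
      ring_n <- max(0L, round(spec$ring_focus_count * eff$count_mult))
      if (ring_n < 4L) {
        warn(paste0("T2A ring has only ", ring_n,
                    " foci: degenerate ring (flagged in ground truth)"))
        degenerate_ring <- TRUE
      }
      base_n <- max(1L, n_eff - ring_n)
      pts <- sample_points_in_mask(nucleoplasm, base_n, 3 * rad)
      base <- focus_row(pts, draw_radii(base_n, rad),
                        draw_peaks(base_n, intensity), "single")
      ring <- empty[0, 1:6]
      if (ring_n > 0L) {
        center <- attr(masks, "nucleolus_center") %||% {
          ct <- component_table(label_components(masks$nucleolus, 4))
          c(ct$row[1], ct$col[1])
        }
        # place each ring focus on the annulus pixel nearest its target
        # angle, preferring the middle of the band
        ann <- perinucleolar_annulus(masks$nucleolus, masks$nucleus)
        w <- attr(ann, "width_px")
        dmap <- distance_to_mask(masks$nucleolus)
        idx <- which(ann)
        nr_ <- nrow(ann)
        ar <- ((idx - 1L) %% nr_) + 1L
        ac <- ((idx - 1L) %/% nr_) + 1L
        aang <- atan2(ac - center[2], ar - center[1])
        arc <- runif(1, 220, 360) * pi / 180
        start <- runif(1, 0, 2 * pi)
        angs <- start + seq(0, 1, length.out = ring_n) * arc
        pts_r <- t(vapply(angs, function(a) {
          dd <- abs(((aang - a + pi) %% (2 * pi)) - pi)
          near <- which(dd <= quantile(dd, min(1, 20 / length(dd))))
          pick <- near[which.min(abs(dmap[idx[near]] - w / 2))]
          c(ar[pick], ac[pick]) + runif(2, -0.3, 0.3)
        }, numeric(2)))
        ring <- focus_row(pts_r, draw_radii(ring_n, rad),
                          clip01(draw_peaks(ring_n, intensity) * 1.5, 30, 255),
                          "ring")
      }
      bind_rows(base, ring)
    },
    T2B = {
      if (n_eff < 2L) {
        pts <- sample_points_in_mask(erode_mask(masks$nucleus, margin),
                                     n_eff, 3 * rad)
        focus_row(pts, draw_radii(n_eff, rad), draw_peaks(n_eff, intensity),
                  "single")
      } else {
        share <- sum(masks$nucleolus) / sum(masks$nucleus)
        n_no <- max(ceiling(0.1 * n_eff),
                    rbinom(1, n_eff, share))
        n_no <- min(n_no, n_eff - 1L)
        pts_no <- sample_points_in_mask(inner_no, n_no, 3 * rad)
        pts_np <- sample_points_in_mask(nucleoplasm, n_eff - n_no, 3 * rad)
        bind_rows(
          focus_row(pts_no, draw_radii(n_no, rad),
                    draw_peaks(n_no, intensity), "single"),
          focus_row(pts_np, draw_radii(n_eff - n_no, rad),
                    draw_peaks(n_eff - n_no, intensity), "single"))
      }
    },
    T3 = {
      k <- max(1L, spec$cluster_count)
      span <- spec$cluster_span_px
      n_single <- max(1L, round(0.2 * n_eff))
      per_cluster <- max(3L, round((n_eff - n_single) / k))
      seed_region <- erode_mask(masks$nucleus,
                                ceiling(span / 2 + rad)) &
        !dilate_mask(masks$nucleolus, 2L)
      if (!any(seed_region)) seed_region <- nucleoplasm
      seeds <- sample_points_in_mask(seed_region, k, span * 1.2)
      step_rng <- if (eff$cluster_tight) c(1.2, 1.8) else c(2.6, 3.2)
      clusters <- map(seq_len(k), function(i) {
        pts <- matrix(seeds[i, ], 1, 2)
        while (nrow(pts) < per_cluster) {
          base <- pts[sample.int(nrow(pts), 1L), ]
          placed <- FALSE
          for (try in seq_len(100)) {
            stp <- runif(1, step_rng[1], step_rng[2]) * rad
            a <- runif(1, 0, 2 * pi)
            cand <- base + stp * c(cos(a), sin(a))
            dr <- cand - seeds[i, ]
            inside <- cand[1] >= 1 && cand[2] >= 1 &&
              cand[1] <= nrow(masks$nucleus) &&
              cand[2] <= ncol(masks$nucleus) &&
              masks$nucleus[round(cand[1]), round(cand[2])] &&
              !masks$nucleolus[round(cand[1]), round(cand[2])]
            if (inside && sqrt(sum(dr^2)) <= span / 2) {
              pts <- rbind(pts, cand)
              placed <- TRUE
              break
            }
          }
          if (!placed) break
        }
        m <- nrow(pts)
        focus_row(pts, draw_radii(m, rad), draw_peaks(m, intensity),
                  "cluster", i)
      })
      pts_s <- sample_points_in_mask(nucleoplasm, n_single, 3 * rad)
      bind_rows(c(clusters, list(
        focus_row(pts_s, draw_radii(n_single, rad),
                  draw_peaks(n_single, intensity), "single"))))
    })

  # optional linear formations: 2-5 collinear foci with slight clustering
  if (spec$linear_formation_count > 0L) {
    lines <- map(seq_len(spec$linear_formation_count), function(i) {
      for (try in seq_len(50)) {
        m <- sample(2:5, 1)
        spacing <- 2.1 * rad
        start <- sample_points_in_mask(nucleoplasm, 1, 0)
        a <- runif(1, 0, 2 * pi)
        pr <- start[1] + (seq_len(m) - 1) * spacing * cos(a)
        pc <- start[2] + (seq_len(m) - 1) * spacing * sin(a)
        ok <- all(pr >= 1 & pc >= 1 & pr <= nrow(masks$nucleus) &
                    pc <= ncol(masks$nucleus)) &&
          all(masks$nucleus[cbind(round(pr), round(pc))])
        if (ok)
          return(focus_row(cbind(pr, pc), draw_radii(m, rad),
                           draw_peaks(m, intensity), "linear"))
      }
      focus_row(matrix(numeric(0), ncol = 2), double(), double(),
                character())
    })
    foci <- bind_rows(c(list(foci), lines))
  }

  foci$in_nucleolus <-
    masks$nucleolus[cbind(pmin(pmax(round(foci$row), 1), nrow(masks$nucleus)),
                          pmin(pmax(round(foci$col), 1),
                               ncol(masks$nucleus)))]
  attr(foci, "degenerate_ring") <- degenerate_ring
  foci
}

#' Render the marker (immunofluorescence) channel
#'
#' Each planted focus becomes an isotropic Gaussian spot (peak at the planted
#' intensity, sd = radius / 2) on an autofluorescence floor at
#' `background_level`.  A `"LIGHT"` nucleolus adds a diffuse elevation inside
#' the nucleolus body; `"DARK"` adds none.  Overlapping spots combine by
#' maximum so a focus centroid renders exactly at its planted peak.
#'
#' @param foci Tibble from [plant_foci()] (may be empty).
#' @inheritParams render_chromatin_channel
#' @return Integer matrix in \[0, 255\].
#' @export
render_marker_channel <- function(foci, masks, spec, seed = 1L) {
  nr <- nrow(masks$nucleus); nc <- ncol(masks$nucleus)
  base <- matrix(spec$background_level, nr, nc)
  if (spec$nucleolus_appearance == "LIGHT")
    base[masks$nucleolus] <- spec$background_level +
      spec$light_nucleolus_level
  img <- base
  if (nrow(foci) > 0) {
    if (any(foci$row < 1 | foci$row > nr | foci$col < 1 | foci$col > nc))
      abort("planted focus outside image bounds")
    for (i in seq_len(nrow(foci))) {
      sigma <- foci$radius_px[i] / 2
      w <- ceiling(4 * sigma)
      rr <- max(1, floor(foci$row[i] - w)):min(nr, ceiling(foci$row[i] + w))
      cc <- max(1, floor(foci$col[i] - w)):min(nc, ceiling(foci$col[i] + w))
      dr <- outer(rr - foci$row[i], cc - foci$col[i],
                  function(a, b) a^2 + b^2)
      spot <- foci$peak[i] * exp(-dr / (2 * sigma^2))
      img[rr, cc] <- pmax(img[rr, cc], spot)
    }
  }
  withr::with_seed(seed, {
    if (spec$noise_sd > 0)
      img <- img + rnorm(length(img), 0, spec$noise_sd)
  })
  as_uint8(img)
}

#' Simulate one two-channel nucleus with ground truth
#'
#' Runs geometry, chromatin rendering, focus planting and marker rendering
#' with independent RNG streams derived from a single seed.
#'
#' @inheritParams make_geometry
#' @param labeled If `FALSE`, no foci are planted and the marker channel
#'   carries autofluorescence only.
#' @return A `synthetic_nucleus` list: `image` ([nucleus_image()]), `masks`,
#'   `foci` (planted ground truth), `spec`, `labeled`.
#' @export
simulate_nucleus <- function(spec, seed = 1L, labeled = TRUE) {
  masks <- make_geometry(spec, derive_seed(seed, 1L))
  chrom <- render_chromatin_channel(masks, spec, derive_seed(seed, 2L))
  foci <- if (labeled) plant_foci(masks, spec, derive_seed(seed, 3L)) else {
    f <- plant_foci(masks, modifyList(spec, list(focus_count = 0)),
                    derive_seed(seed, 3L))
    f
  }
  marker <- render_marker_channel(foci, masks, spec, derive_seed(seed, 4L))
  structure(list(image = nucleus_image(chrom, marker),
                 masks = masks, foci = foci, spec = spec,
                 labeled = labeled && nrow(foci) > 0),
            class = "synthetic_nucleus")
}
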