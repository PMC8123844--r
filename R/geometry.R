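# Geometry stage of the synthetic generator: nucleus / nucleolus ellipses and
# the heterochromatin blob mask.

ellipse_mask <- function(dim, center, axes, theta) {
  nr <- dim[1]; nc <- dim[2]
  r <- matrix(seq_len(nr), nr, nc) - center[1]
  co <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  u <- r * cos(theta) + co * sin(theta)
  v <- -r * sin(theta) + co * cos(theta)
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

#' Generate nucleus, nucleolus and heterochromatin masks
#'
#' Draws the nucleus and nucleolus as ellipses with small random position and
#' orientation jitter (<= 20 degrees), then builds a heterochromatin mask from
#' `hc_blob_count` blob seeds placed in the nucleoplasm.  Each blob carries a
#' scaled distance field; the mask takes exactly
#' `round(hc_target_fraction * nucleus_area)` nucleoplasm pixels with the
#' smallest scaled distance, so the realized heterochromatin fraction matches
#' the target to within one pixel (always inside the +/- 0.01 contract).
#'
#' @param spec A [nucleus_spec()].
#' @param seed Integer seed; the same seed and spec give bit-identical masks.
#' @return A list with logical matrices `nucleus`, `nucleolus`, `hc` plus the
#'   nucleus/nucleolus centers (`attr`ibutes `nucleus_center`,
#'   `nucleolus_center`).
#' @export
make_geometry <- function(spec, seed = 1L) {
  validate_nucleus_spec(spec)
  withr::with_seed(seed, make_geometry_impl(spec))
}

make_geometry_impl <- function(spec) {
  dim <- spec$dim
  margin <- max(spec$nucleus_axes) + 5
  if (any(dim < 2 * margin))
    abort("image dimensions too small for the requested nucleus axes")
  center <- (dim + 1) / 2 + runif(2, -8, 8)
  theta <- runif(1, -20, 20) * pi / 180
  nucleus <- ellipse_mask(dim, center, spec$nucleus_axes, theta)

  # nucleolus: offset from the nucleus center, retried until fully contained
  no_theta <- theta + runif(1, -20, 20) * pi / 180
  max_off <- 0.35 * (min(spec$nucleus_axes) - max(spec$nucleolus_axes))
  max_off <- max(max_off, 0)
  nucleolus <- NULL
  for (try in seq_len(50)) {
    ang <- runif(1, 0, 2 * pi)
    off <- runif(1, 0, max_off)
    no_center <- center + off * c(cos(ang), sin(ang))
    cand <- ellipse_mask(dim, no_center, spec$nucleolus_axes, no_theta)
    if (!any(cand & !nucleus)) {
      nucleolus <- cand
      break
    }
  }
  if (is.null(nucleolus))
    abort("could not place the nucleolus inside the nucleus")

  hc <- make_hc_mask(spec, nucleus, nucleolus)
  out <- list(nucleus = nucleus, nucleolus = nucleolus, hc = hc)
  attr(out, "nucleus_center") <- center
  attr(out, "nucleolus_center") <- no_center
  out
}

make_hc_mask <- function(spec, nucleus, nucleolus) {
  dim <- dim(nucleus)
  empty <- matrix(FALSE, dim[1], dim[2])
  n_target <- round(spec$hc_target_fraction * sum(nucleus))
  if (n_target == 0) return(empty)
  allowed <- nucleus & !dilate_mask(nucleolus, 1)
  allowed_idx <- which(allowed)
  if (length(allowed_idx) < n_target)
    abort(paste0("cannot place heterochromatin: target ", n_target,
                 " px exceeds the ", length(allowed_idx),
                 " px available outside the nucleolus"))
  k <- max(1L, spec$hc_blob_count)
  centers <- sample(allowed_idx, k, replace = length(allowed_idx) < k)
  w <- rlnorm(k, 0, 0.3)
  base <- sqrt(1.6 * n_target / (pi * sum(w^2)))
  radii <- w * base
  nr <- dim[1]
  pr <- ((allowed_idx - 1L) %% nr) + 1L
  pc <- ((allowed_idx - 1L) %/% nr) + 1L
  cr <- ((centers - 1L) %% nr) + 1L
  cc <- ((centers - 1L) %/% nr) + 1L
  d <- rep(Inf, length(allowed_idx))
  for (i in seq_len(k)) {
    di <- sqrt((pr - cr[i])^2 + (pc - cc[i])^2) / radii[i]
    d <- pmin(d, di)
  }
  pick <- allowed_idx[order(d)[seq_len(n_target)]]
  hc <- empty
  hc[pick] <- TRUE
  hc
}
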