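# Shared helpers: mask algebra, connected components, robust thresholds,
# per-nucleus RNG streams.

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# Quantize a real-valued intensity field to an 8-bit integer matrix.
as_uint8 <- function(x) {
  m <- matrix(as.integer(round(clip01(x))), nrow = nrow(x), ncol = ncol(x))
  m
}

is_mask <- function(x) is.matrix(x) && is.logical(x)

stopifnot_mask <- function(x, what = "mask") {
  if (!is_mask(x)) abort(paste0("`", what, "` must be a logical matrix"))
  invisible(x)
}

mask_area <- function(mask) sum(mask)

# Deterministic per-nucleus RNG stream derived from a single user seed.
# Keeps derived seeds inside the 32-bit integer range.
derive_seed <- function(seed, index) {
  s <- (as.double(seed) * 1000003 + as.double(index) * 7919) %% 2147483629
  as.integer(s)
}

ebi <- function(x) EBImage::Image(x * 1)

mask_of <- function(img) {
  m <- EBImage::imageData(img) > 0.5
  matrix(m, nrow = nrow(m), ncol = ncol(m))
}

fill_holes <- function(mask) mask_of(EBImage::fillHull(ebi(mask)))

erode_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(px) + 1L, shape = "disc")
  mask_of(EBImage::erode(ebi(mask), brush))
}

dilate_mask <- function(mask, px) {
  if (px <= 0) return(mask)
  brush <- EBImage::makeBrush(2L * as.integer(px) + 1L, shape = "disc")
  mask_of(EBImage::dilate(ebi(mask), brush))
}

# Euclidean distance from every pixel to the given mask (0 on the mask).
distance_to_mask <- function(mask) {
  d <- EBImage::distmap(ebi(!mask))
  matrix(EBImage::imageData(d), nrow = nrow(mask), ncol = ncol(mask))
}

# Otsu inter-class-variance split of 8-bit intensities (vector form).
otsu_threshold <- function(values) {
  values <- as.integer(round(values))
  img <- EBImage::Image(matrix(values / 255, ncol = 1))
  thr <- EBImage::otsu(img, range = c(0, 1), levels = 256)
  thr * 255
}

#' Label connected components of a binary mask
#'
#' 4-connected labelling delegates to [EBImage::bwlabel()]; 8-connected
#' labelling (used for foci, where diagonally touching spots merge) is
#' computed from the connected components of the 8-neighbour pixel graph.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of the same shape; 0 is background, components are
#'   numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(out)
  if (connectivity == 4) {
    lab <- EBImage::imageData(EBImage::bwlabel(ebi(mask)))
    return(matrix(as.integer(lab), nr, nc))
  }
  if (connectivity != 8) abort("`connectivity` must be 4 or 8")
  pix_id <- integer(nr * nc)
  pix_id[idx] <- seq_along(idx)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  edges <- list()
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(offs)) {
    dr <- offs[[k]][1]; dc <- offs[[k]][2]
    ok <- r + dr >= 1L & r + dr <= nr & co + dc >= 1L & co + dc <= nc
    nb <- idx[ok] + dr + dc * nr
    nb_id <- pix_id[nb]
    keep <- nb_id > 0L
    if (any(keep)) {
      edges[[length(edges) + 1L]] <-
        cbind(pix_id[idx[ok]][keep], nb_id[keep])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  memb <- igraph::components(g)$membership
  # renumber components in raster order of first appearance
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  out[idx] <- relab[memb]
  out
}

# Remove components smaller than min_px (8-connected by default).
remove_specks <- function(mask, min_px, connectivity = 8) {
  if (!any(mask) || min_px <= 1) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_px)
  matrix(lab %in% keep & mask, nrow(mask), ncol(mask))
}

# Centroids/areas of labelled components as a tibble.
component_table <- function(lab, weights = NULL) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) {
    return(tibble(label = integer(), area_px = integer(),
                  row = double(), col = double()))
  }
  nr <- nrow(lab)
  l <- lab[idx]
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  tibble(label = l, r = r, co = co) %>%
    group_by(.data$label) %>%
    summarise(area_px = n(), row = mean(.data$r), col = mean(.data$co),
              .groups = "drop")
}

log_sum_exp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
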