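test_that("three planted non-overlapping spots are detected as three foci", {
  spec <- clean_spec(focus_count = 3)
  sn <- simulate_nucleus(spec, seed = 20)
  fs <- detect_foci(sn$image, segment_nucleus(sn$image))
  expect_equal(fs$count, 3)
  expect_true(fs$labeled)
})

test_that("a foci-free nucleus yields an empty, unlabeled set", {
  sn <- simulate_nucleus(nucleus_spec(noise_sd = 5), seed = 21,
                         labeled = FALSE)
  fs <- detect_foci(sn$image, segment_nucleus(sn$image))
  expect_equal(fs$count, 0)
  expect_false(fs$labeled)
  expect_equal(fs$coverage_percent, 0)
})

test_that("detected counts track planted counts under noise", {
  pop <- tibble::tibble(profile_type = "T2", n = 20L)
  popn <- generate_population(pop, labeled_fraction = 1, seed = 22,
                              noise_sd = 5,
                              spec_args = list(linear_formation_count = 0))
  ok <- mapply(function(sn, planted) {
    fs <- detect_foci(sn$image, segment_nucleus(sn$image))
    abs(fs$count - planted) <= max(1, 0.1 * planted)
  }, popn$nuclei, popn$truth$planted_focus_count)
  expect_gte(mean(ok), 0.9)
})

test_that("coverage increases when a focus is added", {
  spec <- clean_spec(focus_count = 5)
  masks <- make_geometry(spec, seed = 23)
  chrom <- render_chromatin_channel(masks, spec, seed = 23)
  foci <- plant_foci(masks, spec, seed = 23)
  f4 <- foci[1:4, ]; f5 <- foci
  c4 <- detect_foci(nucleus_image(chrom,
         render_marker_channel(f4, masks, spec, 23)), masks$nucleus)
  c5 <- detect_foci(nucleus_image(chrom,
         render_marker_channel(f5, masks, spec, 23)), masks$nucleus)
  expect_gt(c5$coverage_percent, c4$coverage_percent)
})

test_that("labeling index arithmetic and contracts", {
  expect_equal(labeling_index(c(rep(TRUE, 179), rep(FALSE, 21))), 89.5)
  expect_equal(labeling_index(rep(FALSE, 10)), 0)
  expect_equal(labeling_index(rep(TRUE, 10)), 100)
  expect_error(labeling_index(logical(0)), "empty")
})

test_that("cluster statistics: singletons, one blob, thresholds", {
  fake <- function(areas) structure(list(foci = tibble::tibble(
    area_px = areas)), class = "foci_set")
  all_small <- cluster_stats(fake(rep(10, 6)), median_singleton_area = 10)
  expect_equal(all_small$large_cluster_count, 0)
  expect_equal(all_small$large_cluster_area_fraction, 0)
  one_blob <- cluster_stats(fake(400), median_singleton_area = 10)
  expect_equal(one_blob$large_cluster_area_fraction, 1)
  # fallback absolute threshold when no population median is available
  fb <- cluster_stats(fake(c(10, 60)))
  expect_equal(fb$size_threshold_px, 50)
  expect_equal(fb$large_cluster_count, 1)
})

test_that("line profiles sample marker intensity along a path", {
  spec <- clean_spec()
  masks <- make_geometry(spec, seed = 24)
  center <- round(attr(masks, "nucleus_center"))
  foci <- tibble::tibble(row = center[1], col = center[2], radius_px = 3,
                         peak = 180, role = "single",
                         cluster_id = NA_integer_, in_nucleolus = FALSE)
  img <- nucleus_image(render_chromatin_channel(masks, spec, 24),
                       render_marker_channel(foci, masks, spec, 24))
  prof <- line_profile(img, rbind(c(center[1], 2),
                                  c(center[1], ncol(img$marker) - 1)))
  expect_equal(max(prof), 180)
  # background-only path stays at the autofluorescence floor
  bg <- line_profile(img, rbind(c(2, 2), c(2, 40)))
  expect_true(all(bg == spec$background_level))
  expect_length(line_profile(img, cbind(5, 5)), 1)
  expect_error(line_profile(img, rbind(c(0, 5), c(5, 5))), "bounds")
})

test_that("heatmap export: monotone palette, black outside, deterministic", {
  pal <- flame_palette(256)
  lum <- colSums(grDevices::col2rgb(pal) * c(0.2126, 0.7152, 0.0722))
  expect_true(all(diff(lum) >= -1e-9))
  sn <- simulate_nucleus(clean_spec(), seed = 25)
  nucleus <- segment_nucleus(sn$image)
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  heatmap_export(sn$image, nucleus, p1)
  heatmap_export(sn$image, nucleus, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  arr <- png::readPNG(p1)
  outside <- which(!nucleus)
  expect_true(all(arr[cbind(((outside - 1) %% nrow(nucleus)) + 1,
                            ((outside - 1) %/% nrow(nucleus)) + 1, 1)] == 0))
})

test_that("focus count correlates positively with total area (Poisson counts)", {
  pop <- tibble::tibble(profile_type = "T2", n = 40L)
  popn <- generate_population(pop, labeled_fraction = 1, seed = 26,
                              noise_sd = 0,
                              spec_args = list(linear_formation_count = 0))
  res <- analyze_population(popn)
  ct <- correlate(res$per_nucleus$focus_count,
                  res$per_nucleus$total_focus_area_px,
                  pair = "count ~ total_area")
  expect_gt(ct$r, 0.7)
})
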