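test_that("T1 plants only inside and T2 only outside the nucleolus", {
  for (s in 1:5) {
    spec1 <- clean_spec("T1")
    m1 <- make_geometry(spec1, seed = s)
    f1 <- plant_foci(m1, spec1, seed = s)
    expect_true(all(f1$in_nucleolus))

    spec2 <- clean_spec("T2")
    m2 <- make_geometry(spec2, seed = s)
    f2 <- plant_foci(m2, spec2, seed = s)
    expect_false(any(f2$in_nucleolus))
    expect_true(all(m2$nucleus[cbind(round(f2$row), round(f2$col))]))
  }
})

test_that("T2A ring foci sit in the annulus, span >= 180 degrees, and are brighter", {
  spec <- clean_spec("T2A")
  masks <- make_geometry(spec, seed = 31)
  foci <- plant_foci(masks, spec, seed = 31)
  ring <- dplyr::filter(foci, role == "ring")
  expect_gte(nrow(ring), 4)
  ann <- perinucleolar_annulus(masks$nucleolus, masks$nucleus)
  in_ann <- ann[cbind(round(ring$row), round(ring$col))]
  expect_gte(mean(in_ann), 0.9)
  center <- attr(masks, "nucleolus_center")
  ang <- sort(atan2(ring$col - center[2], ring$row - center[1]))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_gte(2 * pi - max(gaps), pi)  # angular extent
  expect_gt(mean(ring$peak), mean(foci$peak[foci$role == "single"]))
})

test_that("a ring collapsed below 4 foci is degenerate but still generated", {
  spec <- clean_spec("T2A", ring_focus_count = 3, focus_count = 20)
  masks <- make_geometry(spec, seed = 32)
  expect_warning(f <- plant_foci(masks, spec, seed = 32), "degenerate")
  expect_true(attr(f, "degenerate_ring"))
  expect_equal(sum(f$role == "ring"), 3)
})

test_that("T2B occupies both compartments", {
  for (s in 1:5) {
    spec <- clean_spec("T2B")
    masks <- make_geometry(spec, seed = 40 + s)
    f <- plant_foci(masks, spec, seed = 40 + s)
    expect_gt(sum(f$in_nucleolus), 0)
    expect_gt(sum(!f$in_nucleolus), 0)
  }
})

test_that("T3 clusters merge into components much larger than a singleton", {
  spec <- clean_spec("T3", cluster_span_px = 25)
  masks <- make_geometry(spec, seed = 33)
  foci <- plant_foci(masks, spec, seed = 33)
  img <- render_marker_channel(foci, masks, spec, seed = 33)
  fs <- detect_foci(nucleus_image(render_chromatin_channel(masks, spec, 33),
                                  img), masks$nucleus)
  # singleton reference: one focus of the same size rendered alone
  one <- foci[which(foci$role == "single")[1], ]
  img1 <- render_marker_channel(one, masks, spec, seed = 33)
  fs1 <- detect_foci(nucleus_image(render_chromatin_channel(masks, spec, 33),
                                   img1), masks$nucleus)
  expect_gte(max(fs$foci$area_px), 5 * fs1$foci$area_px[1])
})

test_that("HU scales focus count down and PCC restores it partially", {
  counts <- sapply(conditions(), function(cond) {
    spec <- clean_spec("T2", cond, linear_formation_count = 0)
    masks <- make_geometry(spec, seed = 77)
    nrow(plant_foci(masks, spec, seed = 77))
  })
  expect_equal(unname(counts), c(25, 10, 15))
})

test_that("a linear formation is a collinear chain of 2-5 foci", {
  spec <- clean_spec("T2", linear_formation_count = 1)
  masks <- make_geometry(spec, seed = 55)
  f <- dplyr::filter(plant_foci(masks, spec, seed = 55), role == "linear")
  expect_gte(nrow(f), 2)
  expect_lte(nrow(f), 5)
  if (nrow(f) > 2) {
    centered <- scale(cbind(f$row, f$col), scale = FALSE)
    ev <- eigen(crossprod(centered))$values
    expect_lt(min(ev) / max(ev), 0.05)  # near-zero minor axis: collinear
  }
})
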