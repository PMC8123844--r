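test_that("perinucleolar annulus geometry", {
  sn <- simulate_nucleus(clean_spec("T2A"), seed = 30)
  ann <- perinucleolar_annulus(sn$masks$nucleolus, sn$masks$nucleus)
  expect_false(any(ann & sn$masks$nucleolus))
  expect_gt(sum(ann), 0)
  expect_gte(attr(ann, "width_px"), 3)
  expect_error(perinucleolar_annulus(matrix(FALSE, 8, 8),
                                     matrix(TRUE, 8, 8)), "empty nucleolus")
})

test_that("features capture the planted localization", {
  a1 <- analyze_nucleus(simulate_nucleus(clean_spec("T1"), seed = 31)$image)
  expect_equal(a1$per_nucleus$nucleolar_focus_fraction, 1.0)
  expect_equal(a1$per_nucleus$ring_score, 0)

  a2a <- analyze_nucleus(simulate_nucleus(clean_spec("T2A"), seed = 32)$image)
  expect_gte(a2a$per_nucleus$ring_score, 0.5)
  expect_gt(a2a$per_nucleus$ring_intensity_ratio, 1)

  sn <- simulate_nucleus(clean_spec("T2"), seed = 33, labeled = FALSE)
  nucleus <- segment_nucleus(sn$image)
  fs <- detect_foci(sn$image, nucleus)
  expect_error(compute_profile_features(fs, sn$masks, sn$image), "UNLABELED")
})

test_that("decision rules reproduce the five written criteria", {
  base <- tibble::tibble(nucleolar_focus_fraction = 0, ring_score = 0,
                         ring_focus_count = 0L, ring_intensity_ratio = 0,
                         large_cluster_area_fraction = 0,
                         nucleolus_brightness_ratio = 1.0,
                         nucleolus_missing = FALSE)
  # foci only within the nucleolus
  t1 <- classify_profile(dplyr::mutate(base, nucleolar_focus_fraction = 1))
  expect_equal(t1$type, "T1")
  # small foci evenly outside a dark nucleolus
  t2 <- classify_profile(dplyr::mutate(base, ring_score = 0.08))
  expect_equal(t2$type, "T2")
  # large clusters take precedence over everything
  t3 <- classify_profile(dplyr::mutate(base,
    large_cluster_area_fraction = 0.8, ring_score = 0.9,
    ring_focus_count = 8L, ring_intensity_ratio = 2))
  expect_equal(t3$type, "T3")
  # the ring: high score, >= 4 foci, brighter than average
  t2a <- classify_profile(dplyr::mutate(base, ring_score = 0.6,
    ring_focus_count = 6L, ring_intensity_ratio = 1.3))
  expect_equal(t2a$type, "T2A")
  # foci in both compartments of a dark nucleolus
  t2b <- classify_profile(dplyr::mutate(base,
    nucleolar_focus_fraction = 0.2))
  expect_equal(t2b$type, "T2B")
  # no nucleolus: restricted set, flagged
  res <- classify_profile(dplyr::mutate(base, nucleolus_missing = TRUE,
    nucleolus_brightness_ratio = NA_real_, ring_score = NA_real_))
  expect_true(res$type %in% c("T2", "T2B", "T3"))
  expect_true(res$nucleolus_missing)
  expect_match(res$decision_path, "restricted")
})

test_that("classification is invariant to foci ordering", {
  sn <- simulate_nucleus(clean_spec("T2A"), seed = 34)
  nucleus <- segment_nucleus(sn$image)
  nucleolus <- segment_nucleolus(sn$image, nucleus)
  fs <- detect_foci(sn$image, nucleus, nucleolus)
  masks <- list(nucleus = nucleus, nucleolus = nucleolus)
  f1 <- compute_profile_features(fs, masks, sn$image)
  fs_shuf <- fs
  fs_shuf$foci <- fs$foci[rev(seq_len(nrow(fs$foci))), ]
  f2 <- compute_profile_features(fs_shuf, masks, sn$image)
  expect_equal(classify_profile(f1)$type, classify_profile(f2)$type)
  expect_equal(f1$ring_score, f2$ring_score)
})

test_that("type distribution sums to 100 over labeled nuclei per condition", {
  cls <- tibble::tibble(
    condition = c(rep("CONTROL", 4), rep("HU", 3)),
    type = c("T2", "T2", "T1", "UNLABELED", "T3", "T3", "UNLABELED"))
  d <- type_distribution(cls)
  ctrl <- dplyr::filter(d, condition == "CONTROL")
  expect_equal(sum(ctrl$percent), 100)
  expect_equal(ctrl$percent[ctrl$type == "T2"], 100 * 2 / 3)
  expect_equal(unique(ctrl$labeling_index_percent), 75)
  single <- type_distribution(tibble::tibble(condition = "PCC", type = "T2"))
  expect_equal(single$percent, 100)
  # an all-unlabeled condition is flagged, not silently dropped
  und <- type_distribution(tibble::tibble(condition = "HU",
                                          type = c("UNLABELED", "UNLABELED")))
  expect_true(und$undefined)
  expect_true(is.na(und$percent))
})

test_that("every labeled nucleus receives exactly one type with a logged path", {
  for (tp in c("T1", "T3")) {
    a <- analyze_nucleus(simulate_nucleus(clean_spec(tp), seed = 36)$image)
    expect_true(a$per_nucleus$type %in% profile_types())
    expect_gt(nchar(a$per_nucleus$decision_path), 0)
  }
  un <- analyze_nucleus(simulate_nucleus(clean_spec(), seed = 37,
                                         labeled = FALSE)$image)
  expect_equal(un$per_nucleus$type, "UNLABELED")
})
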