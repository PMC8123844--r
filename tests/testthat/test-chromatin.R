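test_that("nucleus segmentation recovers the planted mask", {
  sn <- simulate_nucleus(clean_spec(), seed = 12)
  mask <- segment_nucleus(sn$image)
  expect_gte(jaccard(mask, sn$masks$nucleus), 0.95)
  expect_lt(abs(sum(mask) - sum(sn$masks$nucleus)) / sum(sn$masks$nucleus),
            0.05)
})

test_that("a blank image raises a no-nucleus error", {
  blank <- nucleus_image(matrix(10L, 64, 64), matrix(10L, 64, 64))
  expect_error(segment_nucleus(blank), "no nucleus")
})

test_that("nucleolus segmentation: recovery, emptiness, containment", {
  sn <- simulate_nucleus(clean_spec(), seed = 13)
  nucleus <- segment_nucleus(sn$image)
  no <- segment_nucleolus(sn$image, nucleus)
  expect_gte(jaccard(no, sn$masks$nucleolus), 0.8)
  expect_false(any(no & !nucleus))

  # uniform-intensity nucleus has no dark body -> empty mask is valid
  chrom <- matrix(10L, 128, 128)
  chrom[40:90, 40:90] <- 120L
  flat <- nucleus_image(chrom, matrix(10L, 128, 128))
  nm <- segment_nucleus(flat)
  expect_equal(sum(segment_nucleolus(flat, nm)), 0)
})

test_that("heterochromatin threshold recovers planted area within 5%", {
  spec <- nucleus_spec(hc_target_fraction = 0.2, noise_sd = 5)
  sn <- simulate_nucleus(spec, seed = 14)
  nucleus <- segment_nucleus(sn$image)
  no <- segment_nucleolus(sn$image, nucleus)
  hc <- threshold_heterochromatin(sn$image, nucleus, exclude_mask = no)
  planted <- sum(sn$masks$hc)
  expect_lt(abs(sum(hc) - planted) / planted, 0.05)
  expect_false(any(hc & !nucleus))
})

test_that("constant intra-nucleus histogram warns and yields an empty mask", {
  chrom <- matrix(10L, 128, 128)
  chrom[40:90, 40:90] <- 120L
  img <- nucleus_image(chrom, matrix(10L, 128, 128))
  nm <- segment_nucleus(img)
  expect_warning(hc <- threshold_heterochromatin(img, nm), "degenerate")
  expect_equal(sum(hc), 0)
})

test_that("chromatin metrics are exact pixel arithmetic", {
  nucleus <- matrix(FALSE, 120, 120); nucleus[11:110, 11:110] <- TRUE
  hc <- matrix(FALSE, 120, 120); hc[11:30, 11:110] <- TRUE
  no <- matrix(FALSE, 120, 120)
  m <- chromatin_metrics(list(nucleus = nucleus, nucleolus = no, hc = hc))
  expect_equal(m$nucleus_area_px, 10000)
  expect_equal(m$hc_area_px, 2000)
  expect_equal(m$hc_percent, 20)
  m0 <- chromatin_metrics(list(nucleus = nucleus, nucleolus = no,
                               hc = matrix(FALSE, 120, 120)))
  expect_equal(m0$hc_percent, 0)
  expect_error(chromatin_metrics(list(nucleus = matrix(FALSE, 2, 2),
                                      nucleolus = matrix(FALSE, 2, 2),
                                      hc = matrix(FALSE, 2, 2))),
               "zero nucleus")
})

test_that("recovered HC% is monotone in the planted fraction (noiseless)", {
  rec <- sapply(c(0.05, 0.1, 0.2, 0.3), function(fr) {
    sn <- simulate_nucleus(clean_spec(hc_target_fraction = fr), seed = 15)
    nucleus <- segment_nucleus(sn$image)
    no <- segment_nucleolus(sn$image, nucleus)
    hc <- threshold_heterochromatin(sn$image, nucleus, exclude_mask = no)
    100 * sum(hc) / sum(nucleus)
  })
  expect_true(all(diff(rec) > 0))
})

test_that("identical input image gives identical masks and metrics", {
  sn <- simulate_nucleus(nucleus_spec(noise_sd = 5), seed = 16)
  a <- analyze_nucleus(sn$image)
  b <- analyze_nucleus(sn$image)
  expect_identical(a$masks, b$masks)
  expect_identical(a$per_nucleus, b$per_nucleus)
})
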