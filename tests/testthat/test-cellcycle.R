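test_that("input contracts: positivity and minimum sample size", {
  expect_error(fit_phase_model(c(-1, rep(100, 200))), "positive")
  expect_error(fit_phase_model(rnorm(50, 100, 5)), "100 events")
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  d <- simulate_dna_content(c(0.6, 0.25, 0.15), 4000, seed = 41)
  fit <- fit_phase_model(d$value)
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
  expect_true(fit$converged)
})

test_that("a pure-G1 sample collapses onto the G1 component", {
  d <- simulate_dna_content(c(1, 0, 0), 5000, cv = 0.05, seed = 42)
  fit <- fit_phase_model(d$value)
  expect_gte(fit$fractions[["g1"]], 0.97)
})

test_that("the two-point-mass limit recovers exact event proportions", {
  d <- simulate_dna_content(c(0.7, 0, 0.3), 2000, cv = 0.004, seed = 43)
  fit <- fit_phase_model(d$value)
  p_g1 <- mean(d$value < 150)
  expect_lt(abs(fit$fractions[["g1"]] - p_g1), 0.01)
  expect_lt(abs(fit$fractions[["g2m"]] - (1 - p_g1)), 0.01)
  expect_lt(fit$fractions[["s"]], 0.01)
})

test_that("fractions recover the simulation truth within 2 points", {
  fr <- condition_phase_fractions("CONTROL")
  d <- simulate_dna_content(fr, 10000, cv = 0.05, seed = 44)
  fit <- fit_phase_model(d$value)
  expect_lt(abs(fit$fractions[["s"]] - fr[["s"]]), 0.02)
  expect_lt(abs(fit$fractions[["g1"]] - fr[["g1"]]), 0.02)
  expect_gte(fit$g2_ratio, 1.8)
  expect_lte(fit$g2_ratio, 2.2)
})

test_that("recovery holds across replicate simulations", {
  ok <- sapply(1:8, function(i) {
    fr0 <- c(runif(1, 0.3, 0.7), runif(1, 0.1, 0.4), runif(1, 0.05, 0.3))
    fr <- fr0 / sum(fr0)
    d <- simulate_dna_content(fr, 8000, cv = 0.05, seed = 400 + i)
    fit <- fit_phase_model(d$value)
    all(abs(fit$fractions - fr) < 0.02)
  })
  expect_gte(mean(ok), 0.9)
})

test_that("a G1/G2M-only fit agrees with an independent mixture fitter", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  d <- simulate_dna_content(c(0.7, 0, 0.3), 5000, cv = 0.05, seed = 45)
  fit <- fit_phase_model(d$value)
  mc <- mclust::Mclust(d$value, G = 2, modelNames = "V", verbose = FALSE)
  w_ref <- mc$parameters$pro[order(mc$parameters$mean)]
  expect_lt(abs(fit$fractions[["g1"]] - w_ref[1]), 0.03)
  expect_lt(abs(fit$fractions[["g2m"]] - w_ref[2]), 0.03)
})

test_that("phase report formats percentages that sum to 100", {
  d <- simulate_dna_content(c(0.5, 0.3, 0.2), 3000, seed = 46)
  fit <- fit_phase_model(d$value)
  rep_ <- phase_report(fit)
  expect_equal(rep_$phase, c("G1", "S", "G2M"))
  expect_lt(abs(sum(rep_$percent) - 100), 0.011)
  expect_true(all(rep_$converged))
  # an unconverged fit is reported, with a warning flag
  suppressWarnings(bad <- fit_phase_model(d$value, max_iter = 2))
  expect_false(bad$converged)
  expect_warning(rep_bad <- phase_report(bad), "converge")
  expect_false(any(rep_bad$converged))
})

test_that("tidy and glance expose the fit in broom shape", {
  d <- simulate_dna_content(c(0.5, 0.3, 0.2), 2000, seed = 47)
  fit <- fit_phase_model(d$value)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_equal(sum(td$fraction), 1, tolerance = 1e-9)
  gl <- glance(fit)
  expect_true(all(c("g2_ratio", "cv", "log_likelihood", "converged")
                  %in% names(gl)))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
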