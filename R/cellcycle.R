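# Dean-Jett-Fox-style mixture fit of a univariate DNA-content sample:
# Gaussian G1 and G2M peaks plus an S-phase component modeled as an
# equal-weight grid of Gaussians spanning the inter-peak interval, fitted by
# expectation-maximization with a shared coefficient of variation.

phase_component_pars <- function(mu, r, cv, s_grid) {
  # midpoint grid: S means strictly inside (mu, r*mu) at the centers of
  # s_grid equal sub-intervals, so the grid reaches close enough to both
  # peaks to carry the S mass that accrues there
  j <- (seq_len(s_grid) - 0.5) / s_grid
  means <- c(mu, mu + j * (r * mu - mu), r * mu)
  sds <- c(cv * mu, rep(cv * mu, s_grid), cv * r * mu)
  list(means = means, sds = sds)
}

# Expected complete-data log-likelihood given per-component sufficient
# statistics (n_j, sum x, sum x^2); cheap to evaluate, so the M-step for
# (mu, r, cv) is a bounded quasi-Newton search.
q_function <- function(theta, stats, s_grid) {
  mu <- theta[1]; r <- theta[2]; cv <- theta[3]
  p <- phase_component_pars(mu, r, cv, s_grid)
  q <- 0
  for (j in seq_along(p$means)) {
    nj <- stats$n[j]
    if (nj <= 0) next
    s2 <- p$sds[j]^2
    ss <- stats$sx2[j] - 2 * p$means[j] * stats$sx[j] + p$means[j]^2 * nj
    q <- q - 0.5 * nj * log(2 * pi * s2) - ss / (2 * s2)
  }
  q
}

#' Fit the three-phase DNA-content mixture
#'
#' Maximum-likelihood fit by EM of a mixture with a Gaussian G1 peak at
#' `mu`, a Gaussian G2M peak at `r * mu`, and an S component spread over
#' `s_grid` equal-weight Gaussians with means equally spaced on the open
#' interval `(mu, r * mu)`; all components share the coefficient of
#' variation `cv`.  Weights have a closed-form M-step; `(mu, r, cv)` are
#' updated by a bounded search on the expected complete-data log-likelihood,
#' so the observed log-likelihood is non-decreasing across iterations.
#' `mu` is initialized at the dominant histogram mode and `r` at 2.
#'
#' @param events Positive numeric vector of DNA-content events (>= 100).
#' @param init Optional named list overriding the initialization
#'   (`g1_mean`, `g2_ratio`, `cv`, `fractions`).
#' @param s_grid Number of S-phase grid components.
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood change declaring convergence.
#' @return A `phase_fit` object: `fractions` (named g1/s/g2m, summing to 1),
#'   `g1_mean`, `g2_ratio`, `cv`, `log_likelihood`, `loglik_trace`,
#'   `converged`, `iterations`, `n`.
#' @export
fit_phase_model <- function(events, init = NULL, s_grid = 10,
                            max_iter = 1000, tol = 1e-9) {
  events <- as.numeric(events)
  if (any(!is.finite(events)) || any(events <= 0))
    abort("all events must be positive and finite")
  if (length(events) < 100)
    abort("at least 100 events are required for a stable fit")
  n <- length(events)

  # dominant histogram mode as the G1 peak seed
  h <- graphics::hist(events, breaks = 128, plot = FALSE)
  mu <- init$g1_mean %||% h$mids[which.max(h$counts)]
  r <- init$g2_ratio %||% 2.0
  cv <- init$cv %||% 0.06
  w <- init$fractions %||% {
    g1w <- mean(events <= mu * (1 + 2 * cv))
    g2w <- mean(events >= mu * r * (1 - 2 * cv))
    sw <- max(1 - g1w - g2w, 0.02)
    v <- pmax(c(g1w, sw, g2w), 0.02)
    v / sum(v)
  }
  weights <- c(w[1], rep(w[2] / s_grid, s_grid), w[3])

  lower <- c(0.3 * mu, 1.2, 0.005)
  upper <- c(3 * mu, 2.5, 0.4)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p <- phase_component_pars(mu, r, cv, s_grid)
    logd <- vapply(seq_along(p$means), function(j)
      dnorm(events, p$means[j], p$sds[j], log = TRUE) + log(weights[j]),
      numeric(n))
    ll <- sum(log_sum_exp_rows(logd))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    ll_old <- ll

    resp <- exp(logd - log_sum_exp_rows(logd))
    stats <- list(n = colSums(resp),
                  sx = colSums(resp * events),
                  sx2 = colSums(resp * events^2))
    weights <- pmax(stats$n / n, 1e-12)
    weights <- weights / sum(weights)
    # keep S sub-components equal-weight (one S mixing proportion)
    s_w <- sum(weights[2:(s_grid + 1)])
    weights[2:(s_grid + 1)] <- s_w / s_grid
    opt <- optim(c(mu, r, cv), q_function, stats = stats, s_grid = s_grid,
                 method = "L-BFGS-B", lower = lower, upper = upper,
                 control = list(fnscale = -1))
    if (opt$value >= q_function(c(mu, r, cv), stats, s_grid)) {
      mu <- opt$par[1]; r <- opt$par[2]; cv <- opt$par[3]
    }
  }
  fractions <- c(g1 = unname(weights[1]),
                 s = unname(sum(weights[2:(s_grid + 1)])),
                 g2m = unname(weights[s_grid + 2]))
  if (!converged)
    warn(sprintf("EM did not converge in %d iterations", iter))
  structure(list(fractions = fractions, g1_mean = mu, g2_ratio = r,
                 cv = cv, log_likelihood = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, converged = converged,
                 iterations = iter, n = n, s_grid = s_grid,
                 events = events),
            class = "phase_fit")
}

#' @export
print.phase_fit <- function(x, ...) {
  cat("<phase_fit> n =", x$n, if (x$converged) "(converged)" else
    "(NOT converged)", "\n")
  cat(sprintf("  G1 %.2f%%  S %.2f%%  G2M %.2f%%\n",
              100 * x$fractions["g1"], 100 * x$fractions["s"],
              100 * x$fractions["g2m"]))
  cat(sprintf("  g1_mean %.2f  g2_ratio %.3f  cv %.4f  logLik %.1f\n",
              x$g1_mean, x$g2_ratio, x$cv, x$log_likelihood))
  invisible(x)
}

#' @export
tidy.phase_fit <- function(x, ...) {
  tibble(phase = c("G1", "S", "G2M"),
         fraction = unname(x$fractions),
         percent = round(100 * unname(x$fractions), 2))
}

#' @export
glance.phase_fit <- function(x, ...) {
  tibble(g1_mean = x$g1_mean, g2_ratio = x$g2_ratio, cv = x$cv,
         log_likelihood = x$log_likelihood, converged = x$converged,
         iterations = x$iterations, n = x$n)
}

#' Phase percentages report
#'
#' Fractions scaled to percentages (2 decimals) with model diagnostics; an
#' unconverged fit is still reported, with an explicit warning flag.
#'
#' @param fit A `phase_fit`.
#' @return Tibble: `phase`, `percent`, plus diagnostics columns.
#' @export
phase_report <- function(fit) {
  if (!fit$converged)
    warn("phase_report: fit did not converge; percentages are provisional")
  tidy(fit) %>%
    select("phase", "percent") %>%
    mutate(converged = fit$converged,
           g1_mean = fit$g1_mean, g2_ratio = fit$g2_ratio, cv = fit$cv)
}

#' @describeIn fit_phase_model Histogram of the events with the fitted
#'   mixture density overlaid (components scaled by their weights).
#' @param object A `phase_fit`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @export
autoplot.phase_fit <- function(object, bins = 100, ...) {
  p <- phase_component_pars(object$g1_mean, object$g2_ratio, object$cv,
                            object$s_grid)
  w <- c(object$fractions["g1"],
         rep(object$fractions["s"] / object$s_grid, object$s_grid),
         object$fractions["g2m"])
  grid <- seq(min(object$events), max(object$events), length.out = 512)
  dens <- rowSums(vapply(seq_along(p$means), function(j)
    w[j] * dnorm(grid, p$means[j], p$sds[j]), numeric(length(grid))))
  phase_of <- c("G1", rep("S", object$s_grid), "G2M")
  comp <- purrr::map(c("G1", "S", "G2M"), function(ph) {
    js <- which(phase_of == ph)
    tibble(x = grid, phase = ph,
           density = rowSums(vapply(js, function(j)
             w[j] * dnorm(grid, p$means[j], p$sds[j]),
             numeric(length(grid)))))
  }) %>% list_rbind()
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble(value = object$events),
      ggplot2::aes(x = .data$value, y = ggplot2::after_stat(density)),
      bins = bins, fill = "grey85", color = "grey60") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    color = .data$phase)) +
    ggplot2::geom_line(data = tibble(x = grid, density = dens),
                       ggplot2::aes(x = .data$x, y = .data$density),
                       linewidth = 0.8) +
    ggplot2::labs(x = "DNA content (fluorescence)", y = "density",
                  color = "phase") +
    ggplot2::theme_minimal()
}
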