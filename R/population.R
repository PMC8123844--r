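# Population-level simulation: many nuclei per (type, condition, appearance)
# cell with an exact labeled fraction, and univariate DNA-content samples.

#' Condition-level population composition
#'
#' Default profile-type mixture per condition, expressed as a population
#' specification tibble.  Mixtures encode the observed directional shifts:
#' T2 always the most common; T2A rising from under 10% (control) through 15%
#' (HU) to over 20% (PCC); T1/T2B rising after PCC; T3 falling under HU and
#' further under PCC.
#'
#' @param condition One of [conditions()].
#' @param n Total number of nuclei.
#' @return Tibble with columns `profile_type`, `condition`, `n`.
#' @export
condition_population <- function(condition, n) {
  condition <- match.arg(condition, conditions())
  mix <- switch(condition,
    CONTROL = c(T1 = 0.05, T2 = 0.55, T2A = 0.08, T2B = 0.12, T3 = 0.20),
    HU = c(T1 = 0.05, T2 = 0.52, T2A = 0.15, T2B = 0.13, T3 = 0.15),
    PCC = c(T1 = 0.12, T2 = 0.40, T2A = 0.22, T2B = 0.16, T3 = 0.10))
  # largest-remainder apportionment: non-negative counts summing to n
  raw <- mix * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    bump <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[bump] <- counts[bump] + 1
  }
  tibble(profile_type = names(mix), condition = condition,
         n = as.integer(counts))
}

normalize_population_spec <- function(pop) {
  if (!is.data.frame(pop))
    abort("`pop` must be a data frame with columns profile_type, n")
  if (!all(c("profile_type", "n") %in% names(pop)))
    abort("`pop` needs columns `profile_type` and `n`")
  pop <- as_tibble(pop)
  if (!"condition" %in% names(pop)) pop$condition <- "CONTROL"
  if (any(pop$n < 0)) abort("population counts must be >= 0")
  if (!all(pop$profile_type %in% profile_types()))
    abort("unknown profile_type in population spec")
  if (!all(pop$condition %in% conditions()))
    abort("unknown condition in population spec")
  pop
}

#' Generate a synthetic nucleus population with ground truth
#'
#' Expands a population specification into simulated nuclei.  Exactly
#' `round(labeled_fraction * N)` nuclei carry foci; the remainder get
#' autofluorescence-only marker channels.  Each nucleus draws its own RNG
#' stream from `seed`, so populations are reproducible regardless of
#' generation order.  When `poisson_counts = TRUE` the per-nucleus focus
#' count is drawn as `max(1, Poisson(mean))`, giving the natural count
#' variation seen across real nuclei.
#'
#' @param pop Population specification tibble (`profile_type`, `n`, optional
#'   `condition`, `nucleolus_appearance`), e.g. from [condition_population()].
#' @param labeled_fraction Fraction of nuclei carrying foci, in \[0, 1\].
#' @param seed Integer seed.
#' @param noise_sd Gaussian noise level passed to every nucleus.
#' @param poisson_counts Draw per-nucleus focus counts from a Poisson law.
#' @param spec_args Named list of extra [nucleus_spec()] overrides.
#' @return List with `nuclei` (list of `synthetic_nucleus`) and `truth`, a
#'   tibble with one row per nucleus (id, planted type/condition/appearance,
#'   `labeled` flag, planted focus count, realized heterochromatin fraction,
#'   `degenerate_ring`).
#' @export
generate_population <- function(pop, labeled_fraction = 1, seed = 1L,
                                noise_sd = 5, poisson_counts = TRUE,
                                spec_args = list()) {
  pop <- normalize_population_spec(pop)
  if (labeled_fraction < 0 || labeled_fraction > 1)
    abort("`labeled_fraction` must lie in [0, 1]")
  total <- sum(pop$n)
  if (total == 0L)
    return(list(nuclei = list(), truth = tibble(
      nucleus_id = character(), profile_type = character(),
      condition = character(), nucleolus_appearance = character(),
      labeled = logical(), planted_focus_count = integer(),
      hc_fraction = double(), degenerate_ring = logical())))
  rows <- pop[rep(seq_len(nrow(pop)), pop$n), ]
  n_labeled <- round(labeled_fraction * total)
  labeled <- rep(FALSE, total)
  labeled[withr::with_seed(derive_seed(seed, 0L),
                           sample.int(total, n_labeled))] <- TRUE

  nuclei <- vector("list", total)
  truth <- vector("list", total)
  for (i in seq_len(total)) {
    args <- c(list(profile_type = rows$profile_type[i],
                   condition = rows$condition[i],
                   noise_sd = noise_sd),
              spec_args)
    if ("nucleolus_appearance" %in% names(rows))
      args$nucleolus_appearance <- rows$nucleolus_appearance[i]
    spec <- do.call(nucleus_spec, args)
    if (poisson_counts && labeled[i]) {
      jit <- withr::with_seed(derive_seed(seed, 10L * i + 5L),
                              rpois(1, spec$focus_count))
      spec$focus_count <- max(1L, jit)
    }
    sn <- simulate_nucleus(spec, derive_seed(seed, i), labeled = labeled[i])
    nuclei[[i]] <- sn
    truth[[i]] <- tibble(
      nucleus_id = sprintf("n%04d", i),
      profile_type = spec$profile_type,
      condition = spec$condition,
      nucleolus_appearance = spec$nucleolus_appearance,
      labeled = sn$labeled,
      planted_focus_count = nrow(sn$foci),
      hc_fraction = sum(sn$masks$hc) / sum(sn$masks$nucleus),
      degenerate_ring = isTRUE(attr(sn$foci, "degenerate_ring")))
  }
  list(nuclei = nuclei, truth = list_rbind(truth))
}

#' Simulate a univariate DNA-content sample
#'
#' Draws `n` fluorescence events from a three-phase model: G1 events from
#' `Normal(g1_mean, cv * g1_mean)`, G2M events from
#' `Normal(g2_ratio * g1_mean, cv * g2_ratio * g1_mean)`, and S events
#' uniform on `(g1_mean, g2_ratio * g1_mean)` perturbed by
#' `Normal(0, cv * g1_mean)`.  Non-positive draws are resampled.  The phase
#' of every event is recorded, so the ground-truth phase fractions are the
#' exact multinomial draw.
#'
#' @param fractions Numeric `c(g1, s, g2m)` summing to 1 (see
#'   [condition_phase_fractions()]).
#' @param n Number of events (>= 1).
#' @param g1_mean G1 peak position (arbitrary fluorescence units).
#' @param g2_ratio G2/G1 fluorescence ratio (> 1; ~2 for intact DNA).
#' @param cv Coefficient of variation of the peaks (> 0).
#' @param seed Integer seed.
#' @param m_fraction Optional fraction of mitotic events (<= `g2m`); DNA
#'   content cannot separate M from G2, so this only refines the
#'   ground-truth `phase_detail` column.
#' @return A `dna_sample` tibble (`value`, `phase`, `phase_detail`) with the
#'   simulation parameters and the true fractions stored as attributes.
#' @export
simulate_dna_content <- function(fractions, n, g1_mean = 100,
                                 g2_ratio = 2, cv = 0.05, seed = 1L,
                                 m_fraction = NULL) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3 || any(fractions < 0))
    abort("`fractions` must be three non-negative numbers (g1, s, g2m)")
  if (abs(sum(fractions) - 1) > 1e-9)
    abort("`fractions` must sum to 1")
  if (n < 1) abort("`n` must be >= 1")
  if (g2_ratio <= 1) abort("`g2_ratio` must be > 1")
  if (cv <= 0) abort("`cv` must be > 0")
  if (!is.null(m_fraction) && m_fraction > fractions[3] + 1e-12)
    abort("`m_fraction` cannot exceed the g2m fraction")
  g2_mean <- g2_ratio * g1_mean
  withr::with_seed(seed, {
    phase <- sample(c("G1", "S", "G2M"), n, replace = TRUE, prob = fractions)
    value <- numeric(n)
    draw <- function(idx, fn) {
      while (length(idx) > 0) {
        value[idx] <<- fn(length(idx))
        idx <- idx[value[idx] <= 0]
      }
    }
    draw(which(phase == "G1"),
         function(k) rnorm(k, g1_mean, cv * g1_mean))
    draw(which(phase == "G2M"),
         function(k) rnorm(k, g2_mean, cv * g2_mean))
    draw(which(phase == "S"),
         function(k) runif(k, g1_mean, g2_mean) + rnorm(k, 0, cv * g1_mean))
    detail <- phase
    if (!is.null(m_fraction) && m_fraction > 0) {
      g2m_idx <- which(phase == "G2M")
      p_m <- m_fraction / fractions[3]
      is_m <- runif(length(g2m_idx)) < p_m
      detail[g2m_idx[is_m]] <- "M"
      detail[g2m_idx[!is_m]] <- "G2"
    }
  })
  out <- tibble(value = value, phase = phase, phase_detail = detail)
  attr(out, "true_fractions") <- setNames(fractions, c("g1", "s", "g2m"))
  attr(out, "g1_mean") <- g1_mean
  attr(out, "g2_ratio") <- g2_ratio
  attr(out, "cv") <- cv
  class(out) <- c("dna_sample", class(out))
  out
}
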