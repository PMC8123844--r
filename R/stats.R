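# Cross-condition statistics: Pearson correlations, one-way ANOVA with
# Tukey HSD post-hoc comparisons, and per-condition summaries.

#' Pearson correlation with r-squared
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param pair Optional label for the variable pair.
#' @return One-row tibble: `pair`, `r`, `r_squared`, `n`, `p_value`.
#' @export
correlate <- function(x, y, pair = "x~y") {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("at least 3 observations are required")
  if (sd(x) == 0 || sd(y) == 0)
    abort("undefined correlation: zero variance in a variable")
  ct <- cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  tibble(pair = pair, r = r, r_squared = r^2, n = length(x),
         p_value = ct$p.value)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param data Data frame of per-nucleus measurements.
#' @param variable Name of the numeric response column.
#' @param grouping Name of the grouping column (>= 2 groups, each with >= 2
#'   observations).
#' @param alpha Significance level for the flags.
#' @return List of class `group_comparison`: `variable`, `anova_p`,
#'   `pairwise` tibble (`comparison`, `diff`, `p_adj`, `significant`),
#'   `alpha`.
#' @export
compare_groups <- function(data, variable, grouping = "condition",
                           alpha = 0.05) {
  y <- data[[variable]]
  g <- factor(data[[grouping]])
  if (is.null(y)) abort(paste0("no column `", variable, "`"))
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("at least 2 groups are required")
  if (any(table(g) < 2)) abort("every group needs at least 2 observations")
  if (sd(y) == 0) abort("degenerate response: zero variance")
  fit <- aov(y ~ g)
  anova_p <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- TukeyHSD(fit)$g
  pairwise <- tibble(comparison = rownames(tk),
                     diff = tk[, "diff"],
                     p_adj = tk[, "p adj"],
                     significant = tk[, "p adj"] < alpha)
  structure(list(variable = variable, anova_p = anova_p,
                 pairwise = pairwise, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", x$variable, " ANOVA p =",
      format.pval(x$anova_p), "\n")
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  mutate(x$pairwise, variable = x$variable, anova_p = x$anova_p)
}

#' Per-condition summary of a per-nucleus table
#'
#' Mean and SD of the headline per-nucleus measurements plus the labeling
#' index, per condition.  Every number is recomputable from the per-nucleus
#' table alone.
#'
#' @param per_nucleus Tibble with at least `condition`, `labeled` and the
#'   summarized numeric columns.
#' @param variables Numeric columns to summarize.
#' @return Tibble, one row per condition.
#' @export
condition_summary <- function(per_nucleus,
                              variables = c("focus_count", "mean_focus_area",
                                            "coverage_percent", "hc_percent",
                                            "nucleus_area_px")) {
  if (nrow(per_nucleus) == 0) abort("empty per-nucleus table")
  variables <- intersect(variables, names(per_nucleus))
  per_nucleus %>%
    group_by(.data$condition) %>%
    summarise(
      n_nuclei = n(),
      labeling_index_percent = 100 * mean(.data$labeled),
      across(all_of(variables),
             list(mean = ~mean(.x, na.rm = TRUE),
                  sd = ~sd(.x, na.rm = TRUE))),
      .groups = "drop")
}
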