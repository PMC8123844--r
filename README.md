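# nucleoprofile

Nucleus-level quantification and classification of two-channel
fluorescence microscopy images of plant root-meristem nuclei, with a
ground-truth synthetic generator and a DNA-content cell-cycle mixture fit.

The package targets the analysis used to characterize diphosphorylated
retinoblastoma-like protein (RbS807/811ph) activity in *Vicia faba* nuclei
under replication stress (hydroxyurea, HU) and checkpoint override
(HU + caffeine, PCC):

- **Chromatin channel**: nucleus / nucleolus segmentation and
  heterochromatin thresholding, reporting pixel areas and
  `hc_percent = 100 · hc_area / nucleus_area`.
- **Marker channel**: detection of immunofluorescence foci (8-connected
  components above a robust intra-nucleus threshold), per-nucleus focus
  metrics, the labeling index `LI = 100 · #labeled nuclei / N`, line
  profiles and flame-palette heatmaps.
- **Profile classifier**: each labeled nucleus is assigned one of five
  activity profiles — T1 (foci only inside the nucleolus), T2 (foci only
  outside), T2a (T2 plus a perinucleolar ring of high-intensity foci),
  T2b (foci across the whole nucleus) and T3 (large merged clusters) — by
  an ordered, fully configurable decision rule over localization features.
- **Cell cycle**: a Dean–Jett–Fox-style mixture — Gaussian G1 at µ,
  Gaussian G2M at rµ, and S as ten equal-weight Gaussians spanning
  (µ, rµ), shared CV — fitted by expectation–maximization to univariate
  DNA-content samples, reporting G1/S/G2M fractions.
- **Synthetic generator**: two-channel nucleus images with planted
  geometry, heterochromatin fraction, per-type focus placement and
  HU/PCC effect multipliers, providing exact ground truth for every
  stage; plus a DNA-content event simulator with per-event phase labels.
- **Statistics**: per-condition summaries (mean ± SD), Pearson r / r²,
  one-way ANOVA with Tukey HSD post-hoc tests.

Everything tabular flows as tibbles; fitted objects support
`tidy()` / `glance()` / `autoplot()`.

## Worked example

Simulate one control nucleus with a perinucleolar ring profile, analyze
it blind, and compare with what was planted:

```r
library(nucleoprofile)

sn  <- simulate_nucleus(nucleus_spec("T2A", "CONTROL", noise_sd = 5), seed = 42)
res <- analyze_nucleus(sn$image, nucleus_id = "demo", condition = "CONTROL")
res$per_nucleus[, c("focus_count", "coverage_percent", "hc_percent",
                    "ring_score", "type")]
#>   focus_count coverage_percent hc_percent ring_score type
#> 1          29             5.15         20      0.667  T2A
```

The detector found the 29 planted foci, recovered the planted 20%
heterochromatin fraction exactly, and the ring score (2/3 of the twelve
perinucleolar sectors occupied) classified the nucleus as T2a.

Fit phase fractions from a simulated control DNA-content sample (S and M
indices 26.17% and 8.18%, M folded into G2M, G1 the remainder):

```r
fr  <- condition_phase_fractions("CONTROL")
d   <- simulate_dna_content(fr, 10000, seed = 7)
fit <- fit_phase_model(d$value)
fit
#> <phase_fit> n = 10000 (converged)
#>   G1 65.61%  S 26.18%  G2M 8.20%
#>   g1_mean 100.02  g2_ratio 2.005  cv 0.0504  logLik -41661.4
```

The fitted S fraction (26.18%) recovers the simulated truth (26.17%) to
0.01 points, and the fitted G2/G1 ratio lands at 2.005.

The full pipeline — simulate per-condition populations, analyze every
nucleus, write per-nucleus/per-focus CSVs, condition summaries, type
distributions, correlations, ANOVA + Tukey comparisons and heatmaps — is
one call:

```r
run_pipeline(list(simulate = list(conditions = c("CONTROL", "HU", "PCC"),
                                  n_per_condition = 30, noise_sd = 5)),
             out_dir = "out", seed = 1)
```

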