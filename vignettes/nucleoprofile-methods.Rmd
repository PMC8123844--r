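---
title: "Methods: synthetic nuclei, focus detection, profile classification and the DNA-content mixture fit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic nuclei, focus detection, profile classification and the DNA-content mixture fit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nucleoprofile quantifies two-channel fluorescence images of isolated plant
root-meristem nuclei: a chromatin (DAPI-like) channel carrying nucleus,
nucleolus and heterochromatin morphology, and a marker channel carrying
punctate immunofluorescence foci of a phospho-protein (the motivating assay
is diphosphorylated retinoblastoma-like protein, RbS807/811ph, in *Vicia
faba* under hydroxyurea and hydroxyurea + caffeine treatment). Because no
imaging data are deposited for this assay, the package pairs every analysis
stage with a synthetic generator that plants known ground truth, so each
stage is validated by parameter recovery rather than by reference outputs.

## The synthetic generator

A nucleus is drawn on a 256 x 256 px frame (about 0.1 um/px against the
~10 um scale of the source imagery; the pixel size is metadata only). The
nucleus and nucleolus are ellipses with default semi-axes 55 x 40 px and
18 x 14 px, random sub-pixel centers, and orientation jitter up to 20
degrees; the nucleolus is retried until strictly contained. Real nuclei are
only roughly elliptical, but none of the downstream measurements use
ellipse parameters, so this is the simplest geometry that exercises the
segmentation.

Heterochromatin is planted from `hc_blob_count` (default 12) blob seeds in
the nucleoplasm. Each seed carries a log-normal size weight; the union of
blobs is realized by taking exactly `round(hc_target_fraction *
nucleus_area)` nucleoplasm pixels with the smallest blob-scaled distance.
This construction hits the planted fraction to one pixel (the generation
contract is +/- 0.01) and raises an explicit error when the nucleoplasm
cannot hold the target, rather than silently undershooting.

The chromatin channel renders background at 10, nucleoplasm at 120,
heterochromatin at 200 and the nucleolus at 70 (DAPI-dark), plus Gaussian
read noise (`noise_sd`, default 5) and 8-bit clipping. The marker channel
is an autofluorescence floor at the background level; each planted focus is
an isotropic Gaussian spot with sd = radius/2, combined by maximum so a
focus centroid renders exactly at its planted peak. A "LIGHT" nucleolus
adds a diffuse +30 elevation inside the nucleolus body — the light/dark
nucleolus is a marker-channel property, deliberately separated from the
chromatin-channel darkness used for segmentation.

### The five profiles and the treatment effects

Focus placement encodes the five activity profiles: T1 plants all foci
well inside the nucleolus; T2 only in the nucleoplasm; T2A adds a
perinucleolar ring of brighter (x1.5) foci placed on annulus pixels along
an arc of at least 220 degrees; T2B splits foci between both compartments
(at least 10% in the nucleolus, so the compartment is genuinely occupied
and the planted predicate is assertable from ground truth); T3 grows
chains of overlapping foci around cluster seeds (span 25 px) plus a
minority of singletons. The source observations state directions, not
magnitudes, for the treatment effects, so the multipliers are configurable
defaults: hydroxyurea (HU) scales focus count x0.4 and intensity x0.6;
the caffeine co-treatment (PCC) scales x0.6 / x0.8 and widens intra-cluster
spacing so singular foci remain distinguishable. Rare linear formations
(2–5 collinear foci) default to one per nucleus in the treated series.
Per-type focus counts and radii (e.g. 25 foci of radius 2.5 px for T2) are
free parameters of the emulation, chosen once to reproduce the qualitative
morphology at this frame size.

Populations draw one independent RNG stream per nucleus from a single
seed, so generation is reproducible and order-independent; exactly
`round(labeled_fraction * N)` nuclei carry foci. The default labeling
fractions are the measured series values (0.895 control, 0.352 HU); the
combined series value is not reported and defaults to 0.60, between the
two, matching the observed partial restoration. Per-nucleus focus counts
are Poisson-jittered (minimum 1) so count–area correlations are estimable.

What the generator does *not* emulate: optics (no PSF beyond the Gaussian
spot, no photobleaching), touching nuclei, 3-D structure, and chromatin
texture beyond three flat compartment levels. Passing recovery tests
therefore demonstrates correctness of the measurement chain on images
whose noise model is known, not robustness to real-microscope artifacts.

## Chromatin measurements

Nucleus segmentation is a global Otsu (inter-class variance) threshold of
the chromatin channel, hole filling, then the largest 4-connected
component (minimum 500 px). The nucleolus is the largest dark region
strictly inside the eroded nucleus — pixels below the 20th percentile of
intra-nucleus intensity, minimum 50 px; an empty result is valid.
Heterochromatin is thresholded per nucleus by an Otsu split of
intra-nucleus intensities, with speckles under 4 px removed and a fixed
threshold available for parity with manual ImageJ-style workflows. In the
end-to-end pipeline the segmented nucleolus is excluded from threshold
*estimation* only: with the dark nucleolus included, the intra-nucleus
histogram is trimodal and at low heterochromatin content the bimodal split
locks onto the nucleolus/nucleoplasm boundary instead of the
heterochromatin mode. Areas are pixel counts; `hc_percent = 100 * hc_area
/ nucleus_area`.

## Focus detection and features

Foci are detected inside the segmented nucleus at `median + max(3 * MAD,
40)` of intra-nucleus marker intensity. The MAD term adapts to noise; the
fixed minimum rise of 40 intensity units handles the degenerate noiseless
case (MAD = 0) and keeps diffuse nucleolar elevation (+30) below
threshold. Components use 8-connectivity — merged clusters "flow into each
other", arguing for the permissive choice — with a 3 px minimum. Focus
intensity is recorded both as component mean (used in features) and peak.

Per-nucleus features: fraction of focus centroids inside the nucleolus; a
ring score over 12 equal angular sectors of the perinucleolar annulus
(width `max(3 px, 0.15 * equivalent nucleolus radius)`), counting sectors
that contain at least one annulus focus; the annulus-to-overall intensity
ratio; the large-cluster area fraction (a focus is "large" at 5x the
population median singleton area, absolute fallback 50 px); and the
nucleolus-to-nucleoplasm marker brightness ratio computed over non-focus
pixels.

## The classifier

The five qualitative criteria are operationalized as an ordered rule with
every threshold exposed in `classifier_thresholds()`:

1. **T3** if large-cluster area fraction >= 0.5;
2. **T2A** if ring score >= 0.5 and >= 4 annulus foci and intensity ratio >= 1;
3. **T1** if nucleolar focus fraction >= 0.9;
4. **T2** if nucleolar focus fraction <= 0.05 and brightness ratio < 1.2 (dark nucleolus);
5. **T2B** otherwise.

Precedence puts the two most distinctive morphologies (merged clusters,
the ring) first; remaining ties are genuinely ambiguous in the source
description. The decision path is logged per nucleus. Nuclei without a
segmentable nucleolus skip the ring/nucleolar rules, classify among
{T2, T2B, T3} (landing on T2 when rule 1 fails, since no focus can be
nucleolar) and carry a flag. An empty focus set is `UNLABELED` and is
excluded from the type distribution denominator; because the source figure
does not state its denominator, distributions are reported over labeled
nuclei with an all-nuclei column alongside.

## The DNA-content mixture fit

Phase fractions are estimated from univariate DNA-content samples by a
Dean–Jett–Fox-style mixture: Gaussian G1 at `mu` with sd `cv * mu`,
Gaussian G2M at `r * mu` with sd `cv * r * mu`, and S as ten equal-weight
Gaussians with sd `cv * mu` whose means sit at the midpoints of ten equal
sub-intervals of `(mu, r * mu)`. The midpoint grid matters: with means at
interior grid nodes only, S mass accruing near the peaks is absorbed by
the G1/G2M components and S is underestimated by 3–6 points; the midpoint
convention reaches close enough to both peaks to carry that mass. The
shared `cv` and the single S weight keep the model identifiable.

Fitting is EM: closed-form weight updates (with the S sub-weights
projected to equal shares — the constrained maximizer), and a bounded
L-BFGS-B step on the expected complete-data log-likelihood for
`(mu, r, cv)` using per-component sufficient statistics, accepted only
when it does not decrease the objective, so the observed log-likelihood is
non-decreasing (asserted in tests). `mu` initializes at the dominant
histogram mode, `r` at 2.0 with bounds (1.2, 2.5), `cv` at 0.06 with
bounds (0.005, 0.4). Convergence is a relative log-likelihood change
below 1e-9 (default cap 1000 iterations); an unconverged fit is returned
flagged, and reported with a warning. M cannot be separated from G2 by DNA
content, so the simulator records G2/M detail in ground truth while the
fitter reports combined G2M; the measured M indices are folded into G2M
and G1 is the remainder when building the per-condition reference
fractions.

The simulator draws each event's phase from the requested multinomial
(recorded per event), then G1 and G2M values from their Gaussians and S
values uniform between the peaks plus Gaussian perturbation, resampling
non-positive draws. The fit-vs-simulator S shape mismatch (uniform versus
Gaussian grid) is intentional — it shows the fit is not merely inverting
its own density — and recovery stays within the tested 2-point band at
n = 10,000, cv = 0.05.

## Statistics

Group differences use `stats::aov` with `TukeyHSD` post-hoc pairs at
alpha = 0.05 (the source's stated significance convention; its one
"p > 0.05" phrasing is treated as a typo for the threshold its figure
captions state). Correlations are Pearson r with r^2. Tukey handles
multiplicity within a variable; no correction is applied across variables,
matching the source analysis, and summaries always report n.

## Problem sizes and determinism

The test suite validates recovery at the sizes the analyses use: 200-nucleus
populations for labeling-index recovery (exact at zero noise, +/- 1.5
points at noise sd 5), 100 nuclei per type for classifier accuracy
(>= 95% per type, confusion matrix emitted), 30 nuclei per planted
heterochromatin fraction in {5, 10, 20, 30}% (>= 95% of nuclei within 2
points at noise sd 5), 100-nucleus populations per condition for the
treatment orderings, 10,000-event samples for phase-fraction recovery, and
1,000 null replicates for ANOVA type-I calibration (run at the
summary-statistic level; image-level behavior is covered by the other
suites). Every generator function takes an explicit seed and the full
pipeline is byte-identical under a fixed seed.

## Known limitations

- The classifier thresholds encode qualitative criteria; on real images
  they would need calibration against expert labels.
- Nucleolus segmentation assumes one dominant DAPI-dark body; fragmented
  or absent nucleoli fall back to the restricted classifier.
- The DNA-content model assumes a single cycle (no endoreduplication
  peaks, common in plants) and clean, pre-gated events.
- Synthetic noise is i.i.d. Gaussian; structured background, uneven
  illumination and chromatic misregistration are out of scope.
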