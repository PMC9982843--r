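---
title: "Connectome gradients: model, design choices, and what the synthetic cohort does and does not show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome gradients: model, design choices, and what the synthetic cohort does and does not show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connGradients)
```

## The model

A functional gradient is a continuous axis along which ROIs' whole-brain
connectivity profiles vary. The package estimates gradients by the chain
Pearson connectome → Fisher z → row-wise top-fraction threshold → cosine
affinity → PCA, and compares subjects after Procrustes alignment to a
group template. The underlying assumptions are worth stating plainly:

- **Stationarity within a scan**: a single correlation matrix summarizes
  the scan; no dynamic (windowed) connectivity is modeled.
- **Profile similarity carries the hierarchy**: two ROIs are functionally
  close when their *patterns* of strong connections overlap, which is why
  affinity is computed on thresholded, weighted profiles (zeros included)
  rather than on raw correlations.
- **A common frame exists**: per-subject embeddings are assumed to differ
  from the template by an orthogonal transform only, so Procrustes
  rotation (with reflection, without scaling) suffices to align them.
  Orthogonality also means alignment cannot change any within-subject
  gradient distance computed over all aligned components — the package's
  key self-consistency check.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `thresholdFraction` | 0.10 | fraction of connections each ROI retains (row-wise). 0.10 is the field's convention; results should be re-checked over 0.10–0.20, which `runPipeline` supports by re-running with a different configuration. |
| `nComponents` (k) | 10 | components computed and aligned; primary analyses use components 1–2. |
| `primaryDims` | (1, 2) | the gradient plane used for distances. |
| `fdrAlpha` | 0.05 | BH-FDR level; the family is the N ROIs of one gradient dimension per contrast (per-dimension reporting implies per-dimension families), or the N−1 targets of one seed. |
| `alphaEnter`, `alphaRemove` | 0.05 / 0.05 | symmetric stepwise thresholds; only an overall "P < 0.05" convention exists, so both are configurable. |
| `nPermutations` | 1000 | PLS/GSEA permutations; the plus-one rule bounds any p at 1/(n+1). |

Thresholding is **row-wise** by default: "keep the top 10%" is ambiguous
between per-ROI and matrix-wide cutoffs, and the gradient literature uses
per-ROI retention so that every ROI keeps a profile. A `global = TRUE`
mode is available. Negative z-values can survive thresholding when a row
has few positive entries; they are kept, since discarding them would
silently change row support sizes.

Independent group tests default to Welch's unequal-variance t
(`varEqual = TRUE` recovers the pooled Student test); paired tests are
used for matched pre/post designs. Fisher's exact test follows the
point-probability rule (all tables with probability ≤ observed × (1+1e−7)),
which is both `stats::fisher.test`'s convention and the one that
reproduces the published cohort tables digit-for-digit.

## The synthetic cohort: what it emulates

No imaging, clinical or transcriptomic data ship with the package;
`generateCohort()` produces cohorts whose statistical structure matches
what the analysis assumes, so every downstream stage has a known answer.

**Time series.** Each scan follows a two-factor model
`X[t, i] = u_i f1(t) + v_i f2(t) + ε`, with unit-variance latent signals
and iid Gaussian noise (`noiseSd = 1`). The loading vectors are
`u = cos θ`, `v = 0.95 sin θ` on a ring of ROIs. This choice is
deliberate: with equal-norm ring loadings the noiseless affinity chain is
circulant, so its two leading components span *exactly* the planted
(u, v) plane — parameter-recovery tests then measure estimation error
only, not model mismatch. The slight 0.95 attenuation of the second axis
breaks the within-plane rotation degeneracy so that Gradient-1 is
identified with u at the group level. Alternative designs were examined
and rejected: open-arc layouts leave a systematic ~5% plane distortion
even at the population level, and loadings that fill the plane (rather
than its rim) cannot be recovered linearly at all, because cosine
affinity discards loading magnitude.

**The planted effect.** Scans of tinnitus cases decrease the target ROI's
second-axis loading by `effectSizeDelta = 0.8`. The default target sits
on the u ≈ v diagonal: a target with u ≈ 0 would lose essentially all
latent loading after the shift, decouple from the embedding and produce a
noise-dominated position — the balanced target stays anchored through its
first-axis loading, which is what makes the effect detectable at
FDR-corrected levels with n = 16 per group. Scan-to-scan variability of
the target loading (`loadingSd = 0.3`) provides the individual
differences that the clinical coupling acts on.

**Clinical records.** Tinnitus is assigned to match configured pre/post
prevalences exactly (defaults 18/32 and 21/32, with one resolving case
and new-onset cases making up the difference). A latent severity
`s = −coupling · loading + noise` (default `coupling = 3`) is mapped to
the 25 THI items through ordered thresholds on `s` plus item noise — a
single-severity item model, since no item-level structure is published —
and to a VAS rating clipped to 0–10. With these defaults the recovered
Spearman correlations between the target's Gradient-2 and THI/VAS sit
around −0.4 to −0.6 at n ≈ 39, the same order as published values on
real cohorts; at `coupling = 0` the correlation is null *among tinnitus
cases* (pooling tinnitus-free cases is not a null: they differ in both
loading and score by construction).

**Expression.** Signal genes track a supplied per-ROI alteration map with
positive slopes plus noise; background genes are pure noise; the planted
gene ids are returned as a gene set, giving enrichment analysis a ground
truth.

## What passing tests do not show

The generator makes no attempt to emulate BOLD autocorrelation, scanner
or motion artifacts, spatial smoothness of maps, or tumors. Two
consequences matter for interpretation:

- **Uniform permutation nulls.** The PLS permutation test shuffles ROI
  labels uniformly. Real alteration maps are spatially autocorrelated,
  and uniform nulls are then anticonservative relative to
  autocorrelation-preserving nulls. On the synthetic cohort (no spatial
  autocorrelation beyond the planted axes) the calibration is exact; on
  real data the p-values should be read with this caveat.
- **Variance concentration.** On real cortical data the two leading
  gradients can carry ~69% of profile variance. Under the two-factor
  model with 10% row density this is not reproducible: 10% support width
  caps the angular reach of the cosine affinity, spreading variance over
  harmonics of the planted axes, and the template's Gradient-1+2 share
  settles near 38%. Designs that concentrate variance (block-structured
  loadings) sacrifice monotone recovery of the axes. The tests therefore
  assert dominance of the two leading components, not an absolute share;
  the absolute figure is a property of the generator, not of the method.

## Numerical choices

- Correlations are clipped at |r| = 1 − 1e−7 before `atanh`, so duplicate
  time series cannot produce infinities.
- Thresholding ties break toward the larger value, then the lower column
  index; results are exactly reproducible.
- Each PCA component is oriented so its largest-|loading| entry is
  positive, making unaligned embeddings deterministic. Orientation
  relative to any *external* reference (e.g. a planted axis) remains a
  free sign; comparisons against external axes must fix it explicitly.
- Procrustes uses the SVD solution over rotations *and* reflections; an
  optional isotropic scale is off by default.
- Variance fractions are normalized over all N−1 possible components (so
  reported fractions do not depend on k).
- PLS components are extracted by the standard iterative latent-variable
  scheme; with one response the first weight vector is the response-
  covariance direction, so the fit is deterministic with no tolerance
  sensitivity. Gene expression is standardized per gene inside the fit.
- The enrichment score uses weight exponent 1 on |score|; NES divides the
  observed ES by the mean |ES| of same-sign permutation draws; p-values
  are one-sided on the matching sign with the plus-one rule.
- THI score 0 maps to severity level 0 ("no handicap"): the published
  bins start at 1, but resolved cases need a representable level. Odd
  scores are rejected — the 0/2/4 item coding cannot produce them, and
  the gaps in the published bin edges (17, 37, 57, 77) confirm the
  even-score domain.
- Stepwise selection ties break by candidate order in the feature matrix;
  the LOO report records the configuration for exact rerun.

## Design decisions that were genuinely open

- **Embedding algorithm**: PCA, chosen for reproducibility (deterministic,
  no kernel bandwidth); diffusion-map embeddings are common in this
  literature but introduce tuning that the downstream statistics do not
  need.
- **Pooled case analysis**: pre- and post-operative scans of the same
  patient are treated as independent cases when grouping by tinnitus
  status, mirroring standard practice in the motivating study design; a
  subject-level mixed model would be the stricter alternative and is out
  of scope.
- **Template hygiene**: templates are built from reference scans held out
  of all group comparisons (`generateCohort` labels them `REF`), so
  alignment cannot leak group information.
- **Reliability criterion**: a LOOSWR feature is reliable when it enters
  the model *and* is significant in ≥ 98% of leave-one-out fits; entering
  without significance does not count.

## Problem sizes in the test suite

The suite exercises the default study conditions — 100 ROIs, 175 time
points, 32-scan reference cohorts, 16-per-group comparisons (100
repetitions for the power study), 200 null cohorts for FDR calibration,
50 null datasets for stepwise and permutation calibration — which keep
the full run in the low minutes on a single CPU while leaving every
statistical claim testable at its stated threshold.

## Known limitations

- Distances use the aligned primary plane; if more than two components
  carry signal, `gradientDistance(e, dims = ...)` must be widened
  explicitly.
- `seedDistanceTest` treats the seed's targets as an FDR family per seed;
  multiple seeds are not jointly corrected.
- The stepwise procedure inherits the usual caveats of stepwise
  selection; the leave-one-out reliability criterion mitigates but does
  not remove selection instability.
- Community composition is purely descriptive (fractions over altered
  targets); no spatial null for composition is provided.
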