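---
title: "Resting-state connectivity analysis for crossover trials: models and choices"
author: "crossfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state connectivity analysis for crossover trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossfc)
```

## The problem

A two-treatment, two-period crossover trial acquires resting-state fMRI
immediately before dosing (RS0) and about one hour post-dose (RS1), under
both an active compound and placebo, in randomized sequence order. The
questions are (a) where the brain's highly connected functional hubs sit,
(b) how strongly a predefined seed region (here a centromedial-amygdala-type
seed) couples to the rest of the brain, and (c) whether the drug changes
that coupling from RS0 to RS1 more than placebo does — the time-by-drug
interaction, which is the only contrast in a crossover that is protected
against baseline differences.

`crossfc` implements the analysis side of this design from aligned 4D data
onward. Spatial preprocessing (realignment, normalization, segmentation) is
out of scope: inputs are NIfTI volumes already on a common grid, plus the
realignment parameters the scanner pipeline produced.

## Session-level model

Each session is denoised by one simultaneous voxel-wise least-squares
regression followed by band-pass filtering:

1. **Discard** the first 5 volumes (T1 equilibration).
2. **CompCor**: the pooled white-matter + CSF voxel set is detrended and
   standardized per voxel, and the first 5 principal component time courses
   are kept. A single PCA over the pooled tissue set is used (one
   5-component set, not 5 per tissue).
3. **Motion**: the 6 rigid-body parameters plus their first backward
   differences give 12 regressors. The first difference row is zero.
4. **Scrubbing**: a volume is flagged when composite framewise motion
   exceeds 0.9 mm or the robust z of the global-signal change exceeds 5.
   Composite motion is the translation step norm plus the 65 mm arc length
   of the rotation step. The z uses median/MAD scaling: a plain sd is
   inflated by the very spike it is supposed to detect. Flagged volumes
   enter the regression as one-hot indicator columns
   (scrubbing-by-regression), which exactly zeroes their influence on the
   residuals while preserving the temporal spacing the filter needs.
   Deletion is available (`scrub_method = "delete"`) but is not the
   default.
5. **Detrend + nuisance removal**: intercept, linear trend, 12 motion
   regressors, 5 CompCor components and the spike indicators in one
   regression. The global signal is deliberately **not** removed — global
   signal regression manufactures anti-correlations.
6. **Band-pass**: residuals are filtered to 0.01–0.1 Hz with a 2nd-order
   Butterworth (4-pole band-pass) applied forward and backward
   (zero-phase). The design is the standard analog-prototype / bilinear
   route; coefficients match the common scientific-computing reference
   implementation to machine precision, and tests verify ≥ 20 dB stop-band
   attenuation at 0.005 Hz and ≤ 1 dB pass-band loss at 0.05 Hz.

Quality control excludes a session when flagged volumes exceed 30% of the
time course or any translation parameter exceeds 3 mm, both strict
inequalities (boundary values are kept). The 3 mm rule is applied to the
translations; rotations (radians) are reported but do not trigger it.
A subject with any excluded session is dropped from the group stage, since
the interaction needs all four cells.

## Derived maps

**gFCD** (global functional connectivity density): for voxel $i$ in the
gray-matter mask, $K_i = \#\{j \ne i : C_{ij} > r\}$ with $C_{ij}$ the
Pearson correlation of the cleaned series and $r = 0.6$ by default
(robustness settings 0.4 and 0.5). Ties at the threshold and negative
correlations never count. $K$ is normalized by the gray-matter mean,
$K/K_0$, so the mask-wide mean of the normalized map is exactly 1.
Correlations are computed blockwise on standardized series, so the result
is exact and independent of the block size; an $O(V^2)$ double-loop oracle
confirms equality in tests.

**Seed FC**: the unweighted mean cleaned series over the seed mask is
correlated with every voxel and Fisher-transformed, $z = \mathrm{atanh}(r)$,
with $|r|$ clamped at $1 - 10^{-7}$ so seed self-voxels stay finite. Under
independence $z$ has sd $\approx 1/\sqrt{T-3}$.

Both derived maps — never the raw time series — are smoothed with an 8 mm
FWHM Gaussian before statistics. Smoothing divides by the smoothed all-ones
volume, so constant maps are preserved and edges are not darkened.
Normalization precedes smoothing for gFCD.

## Group-level inference

The 2x2 within-subject ANOVA interaction with between-subject covariates is
operationalized as the per-subject difference of differences
$$\Delta_s = (\text{verum}_{RS1} - \text{verum}_{RS0}) -
             (\text{placebo}_{RS1} - \text{placebo}_{RS0}),$$
regressed voxel-wise on an intercept, mean-centered age and a mean-centered
sequence indicator. The interaction T is the intercept over its standard
error with $n - 3$ degrees of freedom. Without covariates this reduces to
the paired t on $\Delta_s$, whose square equals the classical
repeated-measures interaction F — verified against `stats::aov` on a
6-subject fixture. Main effects of time and drug use the analogous
cell-average contrasts.

Cluster-level family-wise error correction is by **sign-flipping
permutation** rather than random-field theory: under the null the
$\Delta_s$ maps are sign-symmetric, so flipping subject signs and
recomputing the covariate-adjusted T map gives an exact null distribution
of the maximum cluster extent (18-connectivity, positive and negative
suprathreshold sets labelled separately, maximum taken over both signs).
The voxel height threshold is the two-sided $p < 0.001$ Student quantile;
$p_{FWE} = (1 + \#\{k_{perm} \ge k\})/(1 + B)$. This replaces the original
toolchain's random-field machinery deliberately: permutation is exact under
exchangeability and its calibration is testable at desk scale (the test
suite measures a familywise rejection rate of about 0.04 at nominal 0.05
over 200 null cohorts).

Post hoc tests extract the cluster-mean map value per subject and cell
(after smoothing, matching the map-processing order) and run four paired
comparisons: verum vs placebo at RS0 and RS1, and RS1 vs RS0 within each
drug. Degenerate zero-variance differences report $t = \pm\infty$, $p = 0$
rather than crashing. An exploratory uncorrected mode is available by
setting `height_p = 0.005` and filtering clusters at `k > 10`.

One-sample validation maps test normalized gFCD against 1 (hub maps) and
zFC against 0, with Benjamini–Hochberg FDR or max-statistic permutation FWE
at 0.05.

## The synthetic cohort generator

`sim_config()` / `generate_cohort()` state a world in which every
downstream claim has a planted truth:

* **Grid**: 12x12x12 voxels at 3 mm by default (tests use 10^3). The last
  two x-slabs are white matter, the one before CSF, the rest gray matter.
  No anatomical realism is attempted.
* **Timing**: 355 volumes at TR 2 s (the trial's acquisition), of which the
  pipeline discards 5.
* **Cohort**: 35 subjects by default, split 18 verum-first / 17
  placebo-first; ages uniform on the integers 31–59 (the trial's
  eligibility window).
* **Latent signals**: unit-variance Gaussian processes band-limited to
  0.01–0.1 Hz by Fourier masking, so they survive the analysis filter and
  recovery tests isolate the analysis rather than the generator. Hub
  regions share one latent per hub; the seed region carries latent $u$ and
  the target region $v = \rho u + \sqrt{1-\rho^2}\,w$, so the latent
  correlation is exactly $\rho$ in expectation. The interaction is planted
  by adding `interaction_delta` to $\rho$ in the verum-RS1 cell only.
  Negative coupling is the sign of $\rho$.
* **Nuisance**: white-matter and CSF tissue-wide signals (amplitude 1) leak
  at 15% into every gray-matter voxel — the structure CompCor exists to
  remove. White Gaussian voxel noise has sd 1 by default (tests use 0.3–0.5
  so that effect calibrations are stable at reduced session lengths).
* **Motion**: slow drift plus isolated single-volume spikes at rate 0.02,
  writing a 1.5 mm excursion into the motion file (set `spike_mm > 3` to
  trigger subject exclusion) and an intensity offset into the BOLD at the
  same volumes. Spikes start at volume 2 and are non-adjacent: a
  first-volume excursion or the interior of a sustained excursion has no
  framewise signature, so no detector could flag it.

What the generator does **not** emulate: hemodynamics, scanner drift and
ghosting, spatial autocorrelation of the noise, anatomical atlases, and the
empirical distribution of real resting-state correlations. A green recovery
test therefore establishes that the pipeline recovers what it is pointed
at, not that real data behave like the generator.

Determinism: one `set.seed(rng_seed)` at cohort start; the same config and
seed give byte-identical cohorts, and the pipeline itself is deterministic
given its own `rng_seed` for the permutation draws.

## Numerical choices and degenerate inputs

* Zero-variance voxels: correlation is undefined, so gFCD assigns $K = 0$
  (and they are never counted as neighbours), seed FC assigns $z = 0$; both
  warn. An all-zero-variance mask is an error.
* Fisher clamp at $|r| = 1 - 10^{-7}$; `atanh` of that is about 8.4.
* The nuisance design is checked for rank; a rank-deficient design (e.g.
  duplicated spike columns) is an error, not a silent drop.
* Filter edge effects: odd-reflection padding of 12 samples; series must be
  longer than the padding.
* Cluster tie-breaks: clusters are relabelled in decreasing size order;
  report rows are sorted by $p_{FWE}$, then size. Permutation p-values
  include the identity flip, so the smallest attainable value is
  $1/(1+B)$.
* Effect-size calibration in the recovery tests is done on the atanh scale
  against a dedicated calibration cohort, because band-limited latents have
  fewer effective degrees of freedom than the volume count suggests and a
  closed-form $2/\sqrt{T-3}$ understates the Δ sd.

## Known limitations

* The "intermediate" artifact-detection thresholds (0.9 mm composite,
  z > 5) follow toolbox convention; the exact composite-motion formula of
  the original toolchain is not recoverable, and ours (translation step +
  65 mm rotation arc) is one of several in use. Thresholds are arguments.
* Whether the original analysis scrubbed by regression or deletion is not
  stated; regression is the default here, deletion a flag.
* The covariate handling inside the original flexible-factorial model is
  not recoverable; the difference-score formulation is the declared
  stand-in and is exact for the 2x2 within-subject interaction.
* Region-level ("SPSS-style") and voxel-level ("SPM-style") analyses are
  unified on the same contrast machinery applied to region means or voxel
  maps respectively.
* No NIfTI R package is available in the target environment, so the package
  carries a minimal NIfTI-1 reader/writer (3D/4D, sform, little-endian
  write); it is cross-checked against nibabel in the test suite.
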