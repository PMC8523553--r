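---
title: "Multivoxel correlation structure similarity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivoxel correlation structure similarity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the method answers

Local brain activity carries information not only in how *strongly* voxels
respond but in how their fluctuations *co-vary*. The multivoxel
correlation structure (MVCS) of a region of interest is the $n \times n$
matrix of pairwise Pearson correlations among its $n$ voxel time courses
within one fMRI run. If a learning episode sculpts a local activity
pattern, and that pattern is spontaneously reinstated ("replayed") during
subsequent rest, the correlation structure of the post-task rest run
should resemble the structure seen during the task more than chance would
predict. `mvcsi` implements this logic as a tested pipeline: from raw ROI
voxel time series to preprocessed runs, MVCS matrices, pairwise
similarity indices, and repeated-measures mixed-model inference.

The motivating design is a within-subject motor-learning experiment: on
each of four visits a participant receives one of two theta-burst
stimulation protocols over the dorsolateral prefrontal cortex
(continuous/inhibitory cTBS or intermittent/facilitatory iTBS) and then
practices either a sequential (SEQ) or a pseudorandom (RND) serial
reaction time task, with resting runs before the intervention and after
the task. The four conditions form a 2 (stimulation) x 2 (task) crossing
whose visit order is counterbalanced by a Latin square.

## Similarity index

For one run, `compute_mvcs()` computes all pairwise Pearson correlations
and applies the Fisher transform $z = \operatorname{artanh}(r)$
off-diagonal; the diagonal is stored as zero and never used. The
similarity index (SI) between two runs is the Pearson correlation between
the vectorised *strict upper triangles* of their two MVCS matrices,
Fisher-transformed in turn. Three pairings are assembled per subject,
condition and ROI:

1. **early vs late task practice** — the task run split at the boundary
   between practice block 8's rest period and block 9's onset; sensitive
   to within-session pattern reorganisation;
2. **pre- vs post-intervention rest** — sensitive to intervention-induced
   changes of the resting correlation structure;
3. **entire task run vs post-intervention rest** — the pattern
   persistence ("replay") contrast.

Only the upper triangle enters the SI: the diagonal is infinite under the
Fisher transform, and using the full symmetric matrix would double-count
every pair. A pair of voxels that is perfectly correlated within a run
would make the transform infinite too; such entries are clipped to
$\operatorname{artanh}(1 - 10^{-7})$ with a warning rather than dropping
the voxels, so a single tied pair cannot change the voxel set. When a
voxel is removed in one run only (zero variance after scrubbing), the two
matrices are re-aligned on their shared voxel identifiers before
comparison.

Whether rest-block volumes inside the task run should contribute to the
task MVCS is genuinely open; `mvcsi` includes them (the run is treated as
one continuous time series, and the early/late boundary respects block
annotations), which maximises the data entering each matrix.

## Preprocessing

The pipeline order is fixed: detrend/high-pass -> down-sample (only when
a pairing mixes repetition times) -> motion scrubbing -> gray-matter
voxel selection -> nuisance regression -> pair-level volume matching.
Defaults, all overridable in `pipeline_config()`:

* **High-pass, 1/128 Hz.** Implemented as exact linear projection onto
  the complement of an intercept, a linear trend, and the discrete-cosine
  basis functions with periods longer than 128 s. Detrending is
  first-order; a projection (rather than a recursive filter) makes the
  operation idempotent and keeps the variance non-increasing.
* **Down-sampling.** Linear interpolation of the faster run onto the
  slower run's grid (rest at TR 1 s down to the task TR 2 s for the
  task-rest pairing). Up-sampling is refused, and resampling precedes
  scrubbing so it always acts on a regular grid; motion tables and
  nuisance pools are resampled by the same operator, keeping rows aligned
  by construction.
* **Scrubbing, 0.5 mm.** Framewise displacement is the Power convention:
  sum of absolute backward differences of the translations plus rotations
  converted to arc length on a 50 mm sphere. A volume whose FD exceeds
  the threshold is removed together with the volume that follows it.
* **Gray matter, > 10 %.** Strict inequality; voxel identifiers are
  preserved so runs of one ROI stay element-wise comparable.
* **Nuisance regression.** 24 motion regressors (parameters, squares,
  backward-difference derivatives with a zero first row, squared
  derivatives) plus the first 3 principal-component time courses of each
  of the white-matter and CSF signal pools (6 tissue regressors),
  principal components computed after scrubbing on the retained rows.
  Residualisation is ordinary least squares per voxel; residuals are
  orthogonal to every retained regressor to numerical precision, and
  collinear columns are dropped by QR pivoting with a message.
* **Volume matching.** The run pair's longer member is cut to a centred
  window of $x$ consecutive retained volumes, $x$ the shorter run's
  count, starting at position $\lfloor (N - x)/2 \rfloor$ of the retained
  sequence. Whether matching should operate before or after scrubbing,
  and how "the middle" rounds, admits several readings; `mvcsi` matches
  after scrubbing on the retained sequence with floor rounding, which
  guarantees both outputs are the same length and time-ordered. Pairs
  shorter than 30 matched volumes are declared unusable and reported
  rather than analysed.

ROI utilities mirror the two mask constructions the design needs: a
10 mm-radius sphere of voxel centres around a stimulation target
(`build_sphere_roi()`), and an anterior/posterior subdivision at the
middle slice of the coronal extent (`split_mask_coronal()`, voxels at the
middle slice going to the posterior part).

## Mixed models

SI values are analysed per ROI and pairing with a repeated-measures
linear mixed model: fixed effects of visit order (factor, 4 levels),
stimulation, task and stimulation x task, and within-subject errors over
the four condition cells drawn from a fully parameterised (unstructured)
4 x 4 covariance; subjects are independent and incomplete subjects
contribute their available cells (row deletion, no imputation).
Block-level behavioral measures (mean correct-press reaction time and
accuracy per block) use fixed effects of visit, stimulation, task, block
and the stimulation/task/block interactions, with within-subject
covariance **unstructured(4 conditions) ⊗ compound-symmetry(16 blocks)**.
The compound-symmetry factor is a correlation matrix (unit diagonal):
scale would otherwise be shared between the two Kronecker factors and
the parameters would not be identified.

Estimation is restricted maximum likelihood on an unconstrained
parameterisation — log-Cholesky for the unstructured block, a scaled
logistic transform for the compound-symmetry correlation (bounded below
by $-1/(m-1)$ to keep the matrix positive definite) — optimised by BFGS
with the analytic REML score
$\partial(-2\ell_R)/\partial\theta_j = \mathrm{tr}(P V_j) - y'P V_j P y$.
Starting values come from the covariance of OLS residuals over cells,
which in balanced complete designs is already the REML optimum.

Fixed-effect terms are tested with Type-III Wald F statistics under
sum-to-zero factor coding, the convention of mainstream repeated-measures
software. Denominator degrees of freedom use the Satterthwaite
approximation: for a contrast $c$,
$\nu = 2 (c' \Phi c)^2 / (g' A g)$, with $\Phi$ the fixed-effect
covariance, $g_j = c' \Phi T_j \Phi c$ the analytic gradient
($T_j = X'V^{-1} V_j V^{-1} X$), and $A$ the inverse expected REML
information $\tfrac12 \mathrm{tr}(P V_j P V_k)$. Multi-df terms (visit,
block) decompose $L \Phi L'$ by eigenvectors and combine per-contrast df
by the standard harmonic rule $\nu = 2E/(E - q)$,
$E = \sum_m \nu_m/(\nu_m - 2)$. In the balanced two-condition sub-design
this machinery collapses to the paired $t$ test exactly: $F = t^2$ and
$\nu = n - 1$, which the test suite asserts to $10^{-6}$.

P-values for a given effect are corrected across ROIs with the
Benjamini-Hochberg step-up procedure (`fdr_bh()`, delegating to
`stats::p.adjust`). Follow-up contrasts between two condition cells are
single-df F tests of model-implied cell means evaluated at the average
visit (sum-to-zero coding marginalises the visit factor exactly).

Two caveats are inherent to the model class, not to this implementation.
With few subjects the unstructured 4 x 4 covariance (10 parameters) is
weakly identified and Type-III F tests can be anticonservative — visibly
so below about 10 subjects, where `nlme::gls` reproduces the same
inflated statistics. And numerical equality with any particular
proprietary implementation is not claimed: exact factor coding and
information matrices differ between packages.

## The synthetic-data generator

No human imaging data ships with the package; the generator produces
complete studies with known ground truth instead. Per subject and
condition it emits two resting runs of 300 volumes at TR 1 s flanking a
task run at TR 2 s whose length follows from the simulated behavior (16
practice blocks of 48 key presses, each followed by 15 s of rest —
typically ~345-355 volumes), six-parameter motion with slow random walks
plus sustained position spikes, WM/CSF nuisance pools, gray-matter
probabilities, and a key-press log.

Voxel time courses follow a latent factor model
$x_v(t) = \sum_k w_{vk} s_k(t) + \text{drift} + \gamma_v u(t) +
\varepsilon_v(t)$: the factor time courses $s_k$ are smoothed white noise
(~6 s moving average) — MVCS operates on covariance structure, so no
haemodynamic response model is needed — and the noiseless correlation
structure is fully determined by the loading matrix $W$. Pattern
persistence between two runs is a single knob: run B's loadings are
$\sqrt{\rho}\, W_{shared} + \sqrt{1-\rho}\, W_{new}$ with columns
renormalised, so $\rho = 1$ reproduces the structure exactly and
$\rho = 0$ makes it independent. The three pairings get their own
baseline $\rho$, shifted additively per condition by configurable task,
stimulation and interaction effects (effect-coded, clipped to $[0,1]$);
realised values are recorded as ground truth. Motion spikes additionally
glitch the voxel data on the affected volumes, giving scrubbing something
real to remove; nuisance couplings $\gamma_v$ are drawn per run, as
session-specific gains.

Behavioral reaction times are log-normal around block means following
$A + B e^{-\lambda(b-1)}$ for SEQ (flat at $A + B$ for RND), with a
per-subject baseline offset (SD 40 ms) shared across sessions — this is
what makes block-level observations within a condition correlate, the
quantity the compound-symmetry factor estimates. Defaults
($A = 500$ ms, $B = 150$ ms, $\lambda = 0.35$, accuracy 0.97) give a
task run near 350 volumes and learning curves of realistic shape.

For calibration and power studies that need thousands of replicate
model fits, `simulate_si_study()` draws SI observations directly at the
condition-cell level: grand mean 0.3, between-subject SD 0.10, residual
SD 0.07 (intraclass correlation ≈ 0.67, typical for within-subject fMRI
similarity measures), with effects expressed in units of the within-cell
SD $\sqrt{0.10^2 + 0.07^2} \approx 0.122$. The voxel-level and SI-level
generators share the design and effect coding; the SI-level path skips
the voxel simulation whose properties are validated separately by the
persistence-recovery tests.

What the generator does *not* emulate: spatial autocorrelation beyond
the ROI factor structure, haemodynamic convolution, physiological noise
spectra, multi-region dependence. Passing tests therefore demonstrate
the correctness and statistical calibration of the pipeline, not that
any particular real dataset satisfies the model's assumptions.

## Numerical choices and test scales

* Degenerate inputs: constant voxels are dropped (recorded); a constant
  response yields a flagged degenerate fit with zero F statistics; an
  all-censored run, an empty gray-matter selection, and a matched pair
  under 30 volumes raise typed conditions that the pipeline converts to
  logged omissions, mirroring how dropped runs are tolerated in practice.
* Optimisation: BFGS with relative tolerance $10^{-12}$, Nelder-Mead
  restart on non-convergence, and a fall-back to the starting estimate
  (flagged in `convergence`) if the optimum drifts into numerical
  singularity.
* The test suite runs its simulations at deliberately modest sizes —
  e.g. persistence recovery at 100 voxels x 150 volumes with 50
  replicates per level, calibration at 1000 replicate fits of 19
  subjects, the end-to-end determinism check at 8 subjects with 60- and
  80-voxel ROIs — chosen so the whole suite completes in a few minutes
  while keeping Monte-Carlo error far below the asserted bands.

## Limitations

* The similarity index compares whole-matrix structure; it cannot say
  *which* voxel pairs drive a difference, and between-state comparisons
  (early vs late) cannot distinguish potentiation from disruption.
* Satterthwaite df with an unstructured covariance is approximate; at
  very small $n$ the F tests inflate (see above) and conclusions there
  should lean on the calibrated simulation machinery instead.
* The generator's persistence knob is monotone in expected SI but not
  equal to it; recovery tests are therefore framed as monotonicity and
  rank correlation, not identity.
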