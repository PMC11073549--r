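---
title: "Task-dependent functional correlations from edge time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-dependent functional correlations from edge time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edgets)
```

## The problem

Two tasks can evoke near-identical activation patterns — the same regions
going up and down by the same amounts — while engaging different
interactions *between* regions. Node-level statistics cannot distinguish
these situations. `edgets` implements a pipeline that measures both levels
with the same statistical machinery: a mass-univariate GLM applied once to
regional BOLD series (activation) and once to *edge time series*, the
frame-wise cofluctuations of region pairs (network profile). It also
implements a generalized psychophysiological interaction (gPPI) model as an
independent comparator, group-level inference with family-wise and FDR
control, and a battery of similarity statistics for comparing maps between
tasks, plus a synthetic cohort generator with full ground truth.

## The model

### Edge time series

Let $x_i(t)$ be the denoised signal of region $i$ over $T$ frames and
$z_i(t)$ its z-score (denominator $T-1$). The edge series of the pair
$(i,j)$ is the element-wise product

$$ r_{ij}(t) = z_i(t)\, z_j(t), $$

whose sum over frames divided by $T-1$ is exactly the Pearson correlation
of the parents. An edge series is therefore a temporal decomposition of a
functional connection, and any frame-level regression model that applies
to a node signal applies unchanged to an edge.

The choice of the $T-1$ denominator for standardization is deliberate: it
is what makes the sum-to-correlation identity exact, and the identity is
enforced as a hard invariant in the test suite (tolerance $10^{-10}$).

### The three designs

* **Denoise design** (57 columns for a 280-frame, two-condition run): a
  finite-impulse-response (FIR) task block of 12 lagged stimulus
  indicators per condition (about 24 s of response at TR = 2 s), the
  24-parameter motion expansion (6 rigid-body series, their backward
  differences with the first frame set to zero, and the squares of all
  12), white matter, CSF, global signal, a discrete-cosine drift basis
  keeping harmonics with period strictly above 187 s (5 columns at this
  geometry), and an intercept. Removing the FIR block (`removeTask =
  FALSE`) keeps evoked responses in the edge series; dropping the global
  column (`gsr = FALSE`) disables global signal regression. Denoising is
  one single regression, which avoids reintroducing artifacts that
  sequential residualization can cause. The intercept is always included
  so residuals are mean-zero and the later standardization is well-posed.
* **Activation design** (39 columns): per condition, the boxcar convolved
  with the canonical double-gamma HRF plus its temporal and dispersion
  derivatives, together with the full nuisance set above and an
  intercept.
* **Edge design** (7 columns): intercept plus the two conditions' HRF
  triplets. The intercept captures the intrinsic (task-free) correlation;
  the condition regressors capture condition-dependent shifts in
  cofluctuation. Rest runs use an intercept-only design, whose estimate
  reduces analytically to $(T-1)/T$ times the static Pearson correlation.

### HRF conventions

The kernel is the standard gamma-difference: a response gamma (shape 6,
scale 1 s) minus an undershoot gamma (shape 16, scale 1 s) divided by 6,
supported on 32 s and normalized to unit sum on the TR grid, so a
sustained block's convolved plateau equals 1 and coefficients stay in
signal units. The temporal derivative is a 1-s finite difference in onset
time; the dispersion derivative a finite difference in the width
parameter (step 0.01). Convolution runs at frame resolution by default
(an oversampling factor is available); with 52–60-s blocks the boundary
effects of coarser sampling are negligible. A frame belongs to a block
iff its acquisition time lies in `[onset, onset + duration)` — half-open,
so adjacent blocks never double-count a frame. The FIR basis is the
delta/lag form (lagged indicators), truncated at the run end rather than
wrapped: wrap-around would let late blocks contaminate the run onset,
which has no physiological reading.

### Estimation

Every GLM is ordinary least squares with optional AR(1) prewhitening of
*both* response and design: a single Cochrane–Orcutt pass estimates
$\rho$ per target from the lag-1 autocorrelation of OLS residuals
(clipped to $(-0.999, 0.999)$), then the filter scales the first row by
$\sqrt{1-\rho^2}$ and replaces row $t$ by $\text{row}_t - \rho\,
\text{row}_{t-1}$. $\rho$ is estimated per target independently (a
pooled option exists); residual degrees of freedom are `frames − rank`,
ignoring the small additional loss from estimating $\rho$, which is
standard practice. Internally the whitened solution is assembled from
lag Gram matrices ($X^{*\prime}X^{*} = (1+\rho^2)X'X - \rho^2(x_1x_1' +
x_Tx_T') - \rho(M + M')$ with $M$ the one-lag cross-Gram), which is
algebraically identical to explicit filtering — the equivalence is
asserted in the tests to $10^{-9}$ — but makes mass-univariate loops over
tens of thousands of edges cheap. Targets with exactly zero residual
variance receive a $\pm\infty$ t sentinel (t = 0, p = 1 for a zero
effect) with a warning rather than aborting the loop.

The subject-level contrast of interest is `incongruent − congruent` on
the main HRF columns; derivative columns are nuisance.

### gPPI comparator

For each ordered pair (seed $i$, target $j$), the target series is
regressed on an intercept, the seed series, the task block (both
conditions' HRF triplets), the interaction of the *observed* seed series
with each condition's main HRF regressor, and the covariate block. No
deconvolution is applied before forming the interactions: for block
designs of this duration deconvolution is generally unnecessary, and the
observed-series product is the literal reading of the interaction. Only
the two main-regressor interactions are formed (derivative columns stay
in the task block but are not interacted); the contrast is the
difference of the two interaction coefficients, and the directed matrix
is symmetrized by averaging the $(i,j)$ and $(j,i)$ entries.

### Group level and similarity

Group maps are classical one-sample (or paired-difference) t tests across
subjects, with Holm–Bonferroni (default) or Benjamini–Hochberg masks at
$\alpha = 0.05$; group t values convert to correlations through
$r^2 = t^2/(t^2 + N - 1)$. All tests are two-sided, since effects of both
signs are of interest. The similarity battery comprises Spearman
correlations of unthresholded maps, Dice coefficients of significance
masks (significance only, not sign agreement; a signed variant exists but
is not the default; the Dice of two empty masks is defined as 1),
subject-subsampling curves, edge-subsampling distributions, region-wise
profile correlations (each region's $P-1$-vector of incident edge
statistics), subject-level beta-map similarity with a paired t and
Cohen's d, Mantel tests on $1-\rho$ subject-distance matrices with
permutation p values and confidence intervals from subsampling without
replacement at ratio 0.135, and SNR (group Cohen's d) filters. Subject-
level similarity uses beta rather than t maps because temporal
autocorrelation makes subject-level degrees of freedom vary across
elements; at the group level dof is always $N-1$. The paired t on
similarity values is computed on raw $\rho$ (a Fisher-z option would be
easy to add, but mean $\rho$ is the quantity reported downstream).

In the top-fraction sign-composition test, the selected count is
$\lfloor \text{fraction} \cdot E\rfloor$ with ties broken by element
index. The fraction is a free parameter (default 0.01): descriptions of
this analysis in the field are ambiguous between "10%" and element counts
that correspond to 1%, so both are reachable and neither is hard-coded.
The reported odds ratio is the sample $(ad)/(bc)$ (0.5 continuity
correction if a cell is empty, flagged), with the exact hypergeometric p
value; zero t statistics are excluded from the positive/negative
classification and logged.

## The synthetic cohort generator

The generator emulates the study conditions the pipeline targets:

* task runs of 280 frames at TR = 2 s containing four congruent and four
  incongruent blocks of 52–60 s, each preceded by a 10–17-s fixation
  (incongruent first, as under yoked administration), plus a 150-frame
  rest run;
* a modular intrinsic correlation matrix over 4 systems (within-system
  0.35, between-system 0.05, unit diagonal);
* condition-dependent covariance modulation: a planted set of 40 edges
  whose covariance is raised by 0.3 (correlation scale) during
  incongruent blocks, gated by the raw condition boxcar — whether
  cofluctuations follow the hemodynamic response is an open question, so
  the ungated form is the default and an HRF-gated option exists;
* HRF-convolved evoked means with per-region baseline amplitudes drawn
  $N(0, 1)$ (noise-sd units — block responses on the order of the noise
  sd) and condition differences drawn $N(0, 0.5^2)$;
* AR(1) noise with $\rho = 0.4$, typical of 2-s TR acquisitions;
* nuisance series (random-walk motion, AR(1) white-matter and CSF
  signals) leaking into the regional signals at amplitude 0.1, with the
  global-signal confound computed as the realized mean across regions.

Because two uniform duration ranges of 8 blocks can exceed the run
length, durations are drawn by rejection until the schedule fits —
deterministic under the seed. Planted covariance increments can push the
per-state covariance slightly indefinite; eigenvalues are clipped at
$10^{-6}$ with a warning, so the realized increment can differ slightly
from the nominal 0.3. Effect sizes were chosen for test power, not
calibrated to any real dataset — no public reference distribution exists
for condition-dependent covariance changes.

In **dissociation mode** (the default) tasks A and B share identical
amplitude vectors but disjoint planted edge sets: activation patterns
agree between tasks while network modulation does not, which is exactly
the situation the two-level analysis is designed to detect. The
`compareTasks()` orchestration on such a cohort yields high group-level
activation similarity, near-zero network similarity, and a strongly
significant subject-level paired t — the qualitative signature the
pipeline should recover.

What the generator does *not* emulate: voxel-level structure and spatial
smoothness, hemodynamic nonlinearity, behavioral titration,
subject-specific HRFs or amplitudes (the truth is shared across subjects,
so between-subject variability is purely stochastic), and realistic
graded connectomes (the intrinsic matrix is two-valued, which attenuates
rank-based comparisons against the truth through ties). Passing tests
demonstrate internal consistency and recoverability under these
conditions, not performance on real acquisitions.

## Numerical choices and degenerate inputs

* Z-scoring uses denominator $T-1$ throughout; constant series are a
  labeled error.
* Edge indexing is row-major over the upper triangle with $i<j$; the
  position/pair bijection is exported (`pairToPos`, `posToPair`) and
  round-trips exactly.
* The periodogram is the plain, untapered FFT periodogram of the
  demeaned series (a smoothed option exists), with frequencies in Hz up
  to Nyquist.
* Rank-deficient designs abort with the names of the collinear columns;
  in the gPPI loop a rank-deficient pair is skipped and logged rather
  than aborting the run.
* All stochastic procedures (generator, subsampling, permutations) take
  explicit seeds and are bit-reproducible.

## Problem sizes

The packaged studies run at desk scale: 20 subjects, 40 regions (780
edges), 280 task frames — small enough that the full dissociation
study, repeated across 50 seeded replicates, completes in minutes, and
large enough for the planted-edge ranking AUC and the
activation/network dissociation to be stable. A full-study geometry
(hundreds of subjects, 268 regions, 35,778 edges) is reachable through
`cohortConfig()`; the edge-count and profile-length identities at that
scale are asserted directly in the tests.

## Known limitations

* AR(1) only; no AR(p) or ReML variance modelling.
* The dof adjustment for prewhitening is the standard `frames − rank`;
  subject-level t maps are therefore not used for between-task
  similarity (betas are, matching the group-level practice).
* gPPI estimates effective, directed coupling; symmetrization to compare
  with edge maps averages away genuine asymmetry.
* No cluster-level or network-based statistics; inference is per-element
  with Holm/BH correction.
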