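---
title: "Models and methods: tract strength, causal search, and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: tract strength, causal search, and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tastecircuit)
```

This vignette documents the models the package implements, the assumptions
behind them, the tunable parameters and their defaults, the numerical
choices made where a design was genuinely open, and what the synthetic-data
generators do and do not emulate.

## The circuit and tract connection strength

The package analyses a fixed taste-reward hierarchy of sixteen regions per
hemisphere. Seeds and their allowed ipsilateral targets are a static table
(`allowed_pairs()`): thalamus to the insula subregions and frontal
operculum; each insula subregion to amygdala nuclei, ventral striatum,
medial PFC and four OFC subregions; substantia nigra to ventral striatum;
each amygdala nucleus to hypothalamus, substantia nigra, ventral striatum
and anterior cingulate; each OFC subregion to hypothalamus, ventral
striatum and medial PFC — 49 pairs per hemisphere, 98 tracts in all.
Regions are identified by label and hemisphere only; no atlas coordinates
or voxel masks are handled. Tract enumeration is ordered (left hemisphere
first, then alphabetical seed and target) so outputs are diff-stable.

Probabilistic tractography launches `samples_per_voxel` (default 5000)
Monte-Carlo streamlines per seed voxel; the count reaching a target,
divided by the total number of samples, is the connection probability
`p_st`. The normalized connection strength of a tract is

\[ \mathrm{CS}(s \to t) = \frac{p_{st}}{P_s}\cdot\bar p \cdot \frac{1}{V_t},
\qquad \bar p = \tfrac12 (p_{st} + p_{ts}), \]

with `P_s` the seed's total connection probability and `V_t` the target
volume in voxels. Three choices here were open and are fixed as follows:

* **Grouping.** The operations "divide by total seed probability, multiply
  by the mean bidirectional probability, divide by target volume" do not
  prescribe an order; the package fixes
  `((p_st / P_s) * p_bar) / V_t`, which makes the result linear in the
  bidirectional mean and exactly inverse-linear in target volume (doubling
  `V_t` halves the strength — a tested invariant).
* **Total seed probability.** `P_s` sums over the seed's in-circuit
  targets, i.e. the targets present in its streamline record. Whether a
  whole-brain total would be preferable cannot be decided from the data
  contract; the in-circuit convention keeps the measure self-contained.
* **Reverse runs.** The bidirectional mean needs a target-to-seed run.
  When it is absent the forward probability stands in for the mean, with a
  warning, so a subject with incomplete tracking still yields a full
  98-row pathway table (rows flagged by `status`).

Path-length correction, when enabled, multiplies each count by the tract's
mean path length (millimetres) *before* any probability is formed,
mirroring distance-corrected tracking output. Mean FA along a pathway is
the visitation-count-weighted mean of per-voxel FA, so rarely-visited
fringe voxels carry little weight; an all-zero visitation vector is an
error rather than a silent zero.

## Effective connectivity: search, score, orientation

### The score

For standardized data the model is a linear-Gaussian structural equation
per region; the score of a DAG is the minimized BIC
\( -2\ln(\mathrm{ML}) + k \ln(n) \) with \(k\) the number of directed edges
plus the number of variables. Dropping constants common to all models, the
deviance decomposes by node as \(n \ln \hat\sigma^2\) with
\(\hat\sigma^2\) the ML (1/n) residual variance of the node on its
parents, computed from the per-subject covariance of z-scored columns. Two
consequences are tested exhaustively: all DAGs in one Markov equivalence
class receive identical scores (to 1e-9), and the empty graph has
\(k = p\).

With several subjects every candidate is scored by the arithmetic mean of
per-subject BICs, each subject at its own sample size. Averaging (rather
than concatenating) keeps subject-specific `n` in the penalty and makes
the search invariant to duplicating a subject — a tested property. Each
subject is z-scored per column first, so amplitude differences between
subjects carry no weight.

### The search

Search starts from the empty graph and proceeds over equivalence classes
with the standard insert and delete operators: `Insert(x, y, T)` is valid
when the shared neighbourhood condition (clique) and the semi-directed
path-blocking condition hold; `Delete(x, y, H)` when the retained
neighbourhood is a clique. After each accepted move the pattern is
re-completed (consistent extension by the sink-elimination algorithm, then
v-structures plus the orientation-propagation rules). Score deltas are
local to one node, memoised, and — a tested invariant — sum exactly to the
class-score change along the whole trajectory.

Three scheduling details:

* Forward insertions repeat while some insertion strictly lowers the
  score; deletions likewise; a *turning* pass then tries class-respecting
  edge reversals, expressed as exact-scored composite delete-then-insert
  moves. The three phases repeat in alternation until none improves.
  Every accepted move strictly lowers the score, so termination is
  guaranteed and the score trace is monotone.
* "Strictly lowers" means a delta below −1e−9; the tolerance guards
  against floating-point noise around score-equivalent moves.
* Ties between equally-scoring moves break lexicographically on
  (source label, target label, subset), making the whole search a pure
  function of its input.

On three-variable problems the search provably matches brute-force
enumeration of all 25 labelled DAGs in every one of 200 random datasets
(an acceptance check). At larger sizes greedy search can lock into local
optima when mixed-sign coefficients produce nearly-canceling paths: the
truth class may sit a few BIC units below the found class but behind a
multi-move barrier no single insert, delete or turn crosses. This is a
property of greedy equivalence search itself, not of the scoring; the test
suite therefore measures structure recovery as per-edge adjacency recall
(about 93% at 20 subjects × 200 time points on random 8-node graphs)
rather than demanding exact skeleton equality, which mixed-sign
parameterizations make unattainable in a substantial fraction of
replicates.

### Non-Gaussian orientation

A Markov equivalence class leaves some edges undirected; with non-Gaussian
signals the direction is identifiable pairwise. For an edge \(x - y\) the
package compares the two factorizations by a likelihood-ratio-style
statistic: \(n\) times the difference of summed differential entropies of
(cause, residual) under the two orderings, each entropy evaluated by the
maximum-entropy approximation
\(H(u) \approx H_{\mathrm{gauss}} - k_1(\mathrm{E}\log\cosh u - \gamma)^2
- k_2 (\mathrm{E}\, u e^{-u^2/2})^2\) on standardized values. The true
ordering leaves maximally non-Gaussian components, so the lower-entropy
ordering wins; the statistic is sign-correct for sub-Gaussian (uniform)
and super-Gaussian (Laplace, exponential) margins alike. A
density-specific likelihood — e.g. scoring residuals against a Laplace
density — is *not* used, deliberately: across the two orderings the
Gaussian scale terms cancel exactly (the covariance determinant is
ordering-invariant), leaving only a shape term that rewards
super-Gaussianity and therefore orients sub-Gaussian data backwards.
For Gaussian data the measure concentrates near zero: orientation is then
unidentifiable and the reported measure honestly reflects that.

The post-processor keeps the searched skeleton fixed and re-examines
*every* edge, compelled and reversible alike, processing edges in
decreasing order of evidence and never closing a directed cycle (a
cycle-closing orientation is flipped; the flipped direction can never
itself close a cycle). Search-compelled directions are retained only at
exact ties. Re-examining compelled edges is a deliberate choice: under
mixed-sign parameterizations the search's compelled orientations are
substantially less reliable than the non-Gaussian evidence, and the
re-orientation leaves graphs with many more directed edges at no accuracy
cost — the acceptance study measures ~99% orientation precision and ~95%
correctly-directed recall over 100 random 8-node uniform-noise SEMs at
n = 1000. Orientation precision there is computed among directed output
edges whose endpoints are truly adjacent (the standard orientation metric;
adjacency errors are a separate axis), while recall counts a true edge as
recovered only if present *and* correctly directed.

### Group comparison

`run_effective_connectivity()` fits each group separately and classifies
every recovered vertex pair as `shared`, `group_unique`,
`direction_reversed` or `mixed`. No parametric comparison of edge
coefficients across groups is attempted: group graphs are separate model
fits, and their fitted weights are not on a common likelihood surface.

## Group statistics

`anova_from_summary()` rebuilds the one-way fixed-effects F test from
per-group means, SDs and sizes; it is algebraically identical to classical
ANOVA on the raw data (tested to 1e-9) and reproduces published F values
from published summary rows to rounding. Zero within-group variance with
distinct means yields an explicit infinite-F result rather than an error.
The covariate-adjusted model tests the group factor by the
extra-sum-of-squares F over the covariates-only model; with no covariates
it reduces exactly to one-way ANOVA, and aliased designs fail with the
offending columns named. The Dunnett-T3-style post hoc refers |t| with
Welch degrees of freedom to the studentized maximum modulus approximated
by the independence form \(1-(2\Phi_t - 1)^m\); exact T3 tables differ
across sources, and the approximation is documented as such (its
familywise error is verified by simulation to stay at or below nominal).
Benjamini–Hochberg adjustment delegates to `p.adjust` after range
validation; the test suite checks it against a from-scratch step-up
implementation. The FDR family is whatever p-value vector the caller
assembles; the bundled CLI `stats` subcommand uses one family per run and
records that in its output.

## Synthetic data: what it emulates, what it does not

`generate_sem_timeseries()` draws each time point i.i.d. from
\(x = B^\top x + e\), solved in topological order, with noise families
`gaussian`, `uniform`, `laplace`, `exponential` (centered), all scaled to
unit variance times `noise_scale`. The empirical covariance converges to
the closed form \((I-B^\top)^{-1} D (I-B)^{-1}\) (tested at T = 50 000
within 2% on a unit-floored scale). An optional double-gamma HRF
convolution (TR 2 s) is available but off by default: the causal search
operates on extracted ROI series, and i.i.d. draws keep ground truth
exactly the coefficient matrix. The generator does **not** emulate
autocorrelated BOLD noise spectra, scanner drift, motion, hemodynamic lag
differences between regions, or measurement noise on top of the SEM — so
passing recovery tests demonstrate correctness of the estimator under its
own model, not robustness to fMRI artefacts.

`generate_task_schedule()` produces the 280-trial conditioning schedule
with *exact* counts: 100 sucrose-CS trials (80 reinforced), 100 null-CS
trials (80 unreinforced, 20 with unexpected sucrose), 80 saliva trials
always reinforced, and the first 10 trials fixed as reinforced sucrose
pairings, counted inside the 100/80. Exact counts (rather than i.i.d.
Bernoulli draws) make every invariant deterministic and testable; the
fixed block inside the totals keeps all printed trial counts true
simultaneously.

`generate_streamline_dataset()` draws per-direction baseline connection
probabilities log-uniformly (default range 0.002–0.05, spanning weak to
strong in-circuit tracts), negative-binomial counts around them
(dispersion 20, a realistic overdispersion for repeated tracking), mean
path lengths uniform on 10–80 mm, and seed sizes from the taxonomy's
region volumes. Baselines and path lengths are drawn once per call and
shared across groups and subjects, so group effects — multiplicative
factors on designated tracts, applied to both directions — are the only
systematic group difference; a null dataset yields calibrated group tests
(verified by simulation).

`generate_behavioral_table()` rescales normal draws affinely so each
group's sample mean and SD match the targets *exactly*, turning a printed
summary table into raw data with identical group statistics; the bundled
target table (`behavioral_summary_targets()`) carries the published
demographic and behavioral moments for the three study groups (26/26/25
subjects). Variables are drawn independently: between-variable
correlations are not represented.

All generators are pure functions of their specification and an integer
seed.

## Problem sizes in the test suite

The suite exercises: the full 98-tract pathway pipeline on generated
subjects; 3-node exhaustive search agreement over 200 datasets; score
equivalence over all 4-node DAGs; orientation performance over 100
replicates of 8-node SEMs at n = 1000; structure recovery and
direction-reversal flagging over 50 replicate two-group cohorts at 20
subjects × 200 time points; 2000-replicate null calibration of the
adjusted group test; and 2000-replicate calibration of the regression null.
These sizes keep the whole suite within a few minutes while leaving every
Monte-Carlo margin wide relative to its binomial standard error.

## Known limitations

* Greedy search can return a near-optimal class on adversarial
  (near-canceling) parameterizations; see above. The score itself is
  exact and class-consistent.
* Orientation assumes linear relations with non-Gaussian independent
  noise; for Gaussian data the measure is honestly near zero and edges
  effectively stay as the search left them.
* The Dunnett-T3 reference is an independence approximation of the
  studentized maximum modulus.
* Connection-strength normalization treats the in-circuit target set as
  the seed's universe; absolute values are not comparable to whole-brain
  normalizations.
* The effective-connectivity layer models contemporaneous influence only:
  no lagged/Granger structure, no cyclic models, no latent confounders.
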