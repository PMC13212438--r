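---
title: "Multi-objective tuning of maximum-entropy niche models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-objective tuning of maximum-entropy niche models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmopt)
```

## The model

`enmopt` fits presence–background species distribution models of the
Gibbs / maximum-entropy family. The landscape is a finite set of grid
cells; the model is the log-linear distribution

$$q_\lambda(x) = \frac{\exp(\lambda \cdot f(x))}{Z(\lambda)},
\qquad Z(\lambda) = \sum_{x \in \text{cells}} \exp(\lambda \cdot f(x)),$$

over the cells, where $f(x)$ is a vector of bounded feature transforms
of the environmental variables at cell $x$. The coefficients maximise
the L1-penalised average log-likelihood of the presence records,

$$J(\lambda) = \frac{1}{m}\sum_{i=1}^{m} \lambda \cdot f(x_i)
 - \ln Z(\lambda) - \sum_j \beta_j |\lambda_j|,$$

which is the Lagrangian form of the classical maximum-entropy program:
among all distributions whose feature expectations match the presence
sample within $\beta_j$, pick the one of maximum entropy. The problem is
concave, so the optimum is unique up to flat directions.

Suitability maps use the cloglog transform
$P = 1 - \exp(-e^{H} q_\lambda)$, with $H$ the entropy of the fitted
distribution; a completely uninformed (uniform) model yields
$P = 1 - e^{-1} \approx 0.632$ in every cell, which is a useful sanity
anchor and is asserted in the test suite.

### Features and penalties

Feature classes follow the established presence-background modelling
conventions. With variables min–max scaled to $[0,1]$ using bounds
taken over the full valid landscape (so predictions are defined
everywhere):

* **L** — the scaled variable itself;
* **Q** — its square;
* **P** — all pairwise products of scaled variables;
* **H** — forward hinges $\max(0, (v-t)/(1-t))$ and reverse hinges
  $\max(0, (t-v)/t)$ at $K$ evenly spaced knots $t = k/(K+1)$ per
  variable (default $K = 50$).

The five allowed combinations are L, LQ, H, LQH, LQHP. Threshold and
categorical features are not implemented: the tuning grid never uses
them. Per-feature penalties are

$$\beta_j = \mathrm{RM} \times \mathrm{base}(\text{class}, m) \times
  s_j / \sqrt{m},$$

where $m$ is the training presence count, $s_j$ the feature's standard
deviation over training presences, and $\mathrm{base}$ a lookup table
(linearly interpolated in $m$) shipped as configuration data:
linear/quadratic $\{0,10,30,100\} \to \{1,1,0.2,0.05\}$, product
$\{0,10,17,30,100\} \to \{2.6,1.6,0.9,0.55,0.05\}$, hinge $0.5$
throughout. Features constant over the presences get $\beta_j = 0$;
penalties are exactly linear in RM (asserted in tests).

### The trainer

`fitMaxent()` uses cyclic coordinate ascent. Each coordinate takes a
1-D Newton step on the smooth part of $J$ followed by soft-thresholding
at $\beta_j$; the exact objective change of each proposed update is
computed in $O(n)$ and the step is halved until the change is
nonnegative, so the objective is non-decreasing by construction. A
sweep's largest single-coordinate improvement below `tol` (default
1e-5) stops the fit; `max_iter` (default 1000) caps full sweeps. After
three warm-up sweeps the cycle restricts to the active (nonzero) set
with a full pass every fifth sweep, the usual coordinate-descent
economy; convergence is only declared off a full pass.

Every accepted update's objective gain is credited to the feature's
parent variable (products split 50/50). "Percent contribution" is this
gain ledger normalised to 100 — path-dependent by construction, which is
why the package also reports permutation importance (training-AUC drop
under joint permutation of a variable across presence + background
rows, normalised to 100).

## Evaluation metrics

All metrics treat background cells as pseudo-absences — there are no
true absences in this data type, and the convention is stated
explicitly because TSS on presence-background data is otherwise
ambiguous. Sensitivity counts presences with score $\ge \tau$ (ties
predicted present); specificity counts background with score $< \tau$.

* **AUC** — the Mann–Whitney rank statistic with half-credit ties.
* **MTSS** — the smallest observed score maximising sensitivity +
  specificity; TSS is reported at the training MTSS for both train and
  test scores.
* **OR10** — the threshold is the $(\lfloor 0.1m \rfloor + 1)$-th
  smallest training presence score; omission is the fraction strictly
  below it. At $m = 100$ distinct scores the training rate is exactly
  0.10, a definition-level identity the acceptance suite checks.
* **AICc** — raw predictions are normalised over the full landscape
  grid; $k$ counts nonzero coefficients, $n$ the presences;
  $2k - 2\ln L + 2k(k+1)/(n-k-1)$, $+\infty$ when $n \le k + 1$.

## Hyperparameter tuning

The genotype space is RM $\in \{0.5, 0.6, \dots, 3.0\}$ crossed with
the five feature-class sets — 130 genotypes. Each genotype is scored by
fitting once per train/test replicate (75/25 subsampling without
replacement; the default is 10 replicates) and averaging four
minimisation objectives: $1 - \mathrm{AUC}_{test}$,
$1 - \mathrm{TSS}_{test}$, $\mathrm{OR10}_{test}$, AICc. The 75/25
protocol is subsampling, not resampling with replacement: a held-out
test fraction is only coherent without replacement.

NSGA-III drives the search: uniform crossover (rate 0.9) and per-gene
random-reset mutation (rate 0.5) on the 2-gene chromosome;
environmental selection by non-dominated sorting, adaptive
normalisation (ideal point, achievement-scalarised extreme points,
hyperplane intercepts with a nadir fallback when the system is
degenerate), perpendicular-distance association to Das–Dennis reference
lines ($p = 6$ divisions, 84 points for 4 objectives) and niche-count
selection with random tie-breaks. Default population 92 (the smallest
multiple of 4 at least 84) and 40 generations; both configurable.

Two design choices matter for auditability:

* the evaluator is **memoised** — each genotype is fitted once — and the
  reported archive covers *everything ever evaluated*, not the final
  population. On a 130-point space this makes the search verifiable:
  the acceptance suite checks that the evolved archive's rank-1 set
  equals the exhaustively enumerated Pareto front of a deterministic
  toy evaluator over all 130 genotypes.
* AICc's scale dominates the other objectives by orders of magnitude;
  this is handled by NSGA-III's adaptive normalisation, not by
  pre-scaling, and infinite AICc entries are capped only inside the
  normalisation (domination sees the raw values).

The published studies this framework serves pick their operating point
from the front "comprehensively"; that is not reproducible, so
`selectCompromise()` implements a deterministic stand-in: min–max
normalise the front, pick the member closest to the ideal point, ties
to lower RM then fewer feature classes. The rule is invariant to
positive rescaling of any objective and is labelled as a package
convention in the archive JSON. An `exhaustive` mode is provided since
130 genotypes is enumerable at moderate problem sizes; NSGA-III remains
the default.

The final map comes from a single fit of the selected genotype on all
thinned presences; the replicates are used only for objective
estimation.

## Spatial analytics

**MESS.** Per variable, similarity follows the piecewise empirical
formula on the percentage $f$ of reference values strictly below the
target value: $2f$ for $0 < f \le 50$, $2(100-f)$ for $50 < f < 100$,
and linear extrapolation $100(p - \min)/(\max - \min)$ (resp.
$100(\max - p)/(\max - \min)$) outside the observed range. The cell
score is the minimum over variables; $S \le 0$ flags novel
environments. The reference sample is the training presence +
background values (configurable to presence-only); for a single
variable the score inside the range is the tent function
$200\min(\hat F, 1 - \hat F)$ of the empirical CDF, which the tests
check directly.

**Classification and dynamics.** The MTSS threshold dichotomises
suitable/unsuitable; suitable habitat is stratified into marginal /
moderate / high tiers by half-open intervals (boundary upward). The
published three-tier cut points (0.312941 / 0.523362 / 0.684789) match
no simple generating rule, so tier breaks are explicit configuration
with two built-in generators — equal-interval above the MTSS threshold,
or terciles of the suitable cells — plus the literal published preset.
Range change between periods is coded 0/1/2/3 (never / stable /
expansion / contraction), with the algebraic identities (stable +
expansion = future suitable area) asserted on every synthetic run.
Centroids are area-weighted means of suitable cell centers in lon/lat;
migration steps report haversine distance and initial bearing on a
sphere of radius 6371.0088 km.

**Risk.** Suitability is first constrained — zero where MESS $\le 0$ or
below the MTSS threshold — then multiplied pixel-wise by each species'
density grid. Cells with zero constrained suitability or zero density
are risk-free (class 0); the positive risk values of each species are
partitioned into three classes by Fisher's exact dynamic programme for
Jenks natural breaks (implemented in C++, as the field's classification
packages do), minimising within-class squared deviation over contiguous
partitions, with deterministic every-j-th subsampling above 20 000
values. Because breaks are fitted per species on that species' own
values, risk classes are invariant to any positive rescaling of the
density grid — head per pixel versus head per km² does not change the
map, only the break values.

## Geodata conventions

Grids are north-up WGS84 with cell-center registration; row 1 is the
northernmost row. Misaligned inputs are refused, never resampled — the
numerical core stays auditable, and alignment is a preprocessing
concern. Pixel areas use the spherical-zone formula
$A = R^2 \Delta\lambda (\sin\varphi_{top} - \sin\varphi_{bot})$ with
$R = 6371.0088$ km; the difference from ellipsoidal areas is far below
the 0.01 × 10⁴ km² reporting grain of the area tables. Rasters travel
as ESRI ASCII grids — a plain-text single-band format with an explicit
nodata sentinel (−9999) — written at full double precision so
write/read round-trips are exact.

## The synthetic landscape generator

Every downstream stage is testable without external data. The
generator produces:

* **environmental fields** — deterministic gradients, Gaussian bumps,
  or Gaussian white noise smoothed by a fixed-width moving-average
  kernel (no FFT, so results are identical across platforms); smoothing
  width 5 gives lag-1 spatial autocorrelation around 0.8, in the range
  of real interpolated climate surfaces;
* **presences** — drawn with replacement over valid cells with
  probability $\propto \exp(\lambda_{true} \cdot f)$ for a known
  log-linear truth, at cell centers (sub-cell jitter available but off
  by default so cell bookkeeping is exact). Sampling with replacement
  reproduces the clumping of real occurrence data, which is what
  thinning is tested against;
* **densities** — log-normal positive values with an exact fraction of
  zero cells, mimicking zero-inflated livestock head-count grids.

All outputs are pure functions of (spec, seed). What the generator does
*not* emulate: the covariance structure of real bioclim variables,
climate-model scenario physics (test "scenarios" are additive or
multiplicative perturbations of the base stack), observation bias, and
coordinate error. Passing tests therefore demonstrate algorithmic
correctness — recovery of a known truth under the model's own
assumptions — not predictive skill on real landscapes.

The recovery harness is the decisive end-to-end check: a 50×50 stack
with four variables, 2000 presences from a known coefficient vector,
fitted with linear features at RM = 0.1, must yield fitted coefficients
correlating above 0.9 with the truth (in practice the correlation
exceeds 0.99).

## Screening

Candidate variables are screened on the presence + background sample —
the data the model actually sees. Three instruments are combined in a
fixed, deterministic order (the integrated strategy this reproduces
states no precedence, so the package fixes one):

1. Spearman correlation with the two-sided t-approximation p-value
   ($t = r\sqrt{(n-2)/(1-r^2)}$, $n-2$ df; standard at samples in the
   hundreds). For every pair with $|r| \ge 0.8$ and $p < 0.05$
   (strongest pair first), the member with lower permutation importance
   is dropped (ties: lower percent contribution, then the
   lexicographically later name).
2. Iterative VIF pruning: while any $\mathrm{VIF} = 1/(1-R^2)$ exceeds
   5, drop the worst and recompute.
3. The kept set provably satisfies both invariants, which is asserted
   property-style on random inputs.

## Occurrence handling

Spatial thinning enforces a minimum pairwise great-circle separation
(default 1 km) by randomised greedy maximum retention: repeatedly
delete a point with the most remaining conflicts (random tie-break),
over `n_restarts` passes (default 10), keeping the largest surviving
set. Exact maximum-independent-set is NP-hard and out of scope; on
clouds of up to 12 points the greedy result is checked against
exhaustive subset search in the tests, where it attains the optimum.
Background sampling is uniform without replacement over valid cells
(default 10 000, capped at the valid-cell count with a warning);
presence cells are eligible unless excluded explicitly, matching common
practice. One thinned dataset and one background sample are shared by
all replicates.

## Problem sizes and numerical choices

The test and acceptance suites run scaled-down study conditions chosen
to exercise every code path on one CPU in minutes: 24–50 grids per
side, 80–150 raw presences, 300–500 background cells, 2–3 replicates,
$K = 5$–8 hinge knots, and NSGA-III populations of 20–40 over 8–20
generations. The defaults shipped with the package (10 000 background,
10 replicates, $K = 50$, population 92, 40 generations) are the
full-scale settings a real study would run. Degenerate inputs are
handled explicitly: constant variables are refused by the feature
builder and flagged by screening; constant MESS reference variables
yield a 0/−Inf sentinel with a warning; fewer distinct values than risk
classes fall back to one class per distinct value; empty suitable sets
raise errors rather than NaN centroids.

## Known limitations

* The trainer's percent-contribution ledger is path-dependent (as in
  reference implementations) and should be read qualitatively;
  permutation importance is the robust companion.
* No sample-bias grids, no target-group background, no environmental
  -space thinning, no replicate-averaged ensemble maps.
* No reprojection or resampling; inputs must share one grid.
* The compromise-selection rule is a reproducible convention, not a
  claim about how any published study chose its operating point.
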