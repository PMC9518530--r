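---
title: "Measuring composite regional resilience with projection pursuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring composite regional resilience with projection pursuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resilpp)
```

## The measurement problem

Regional emergency resilience is observed only indirectly, through a panel of
heterogeneous indicators: counts of hospital beds and firefighters,
percentages of insurance or network coverage, monetary stocks of relief
material.  The analyst has a small cross-section — here on the order of 17
regions by 27 indicators grouped into four capacity dimensions (resistance,
restore, adaptability, collaborative) — and wants a single comparable score
per region, weights per indicator that are driven by the data rather than by
expert judgement, and a reading of how the scores arrange themselves in
space.

`resilpp` implements that workflow: orientation-aware min-max
standardization, projection-pursuit weighting and scoring optimized by a
real-coded accelerating genetic algorithm (RAGA), exact Jenks natural-breaks
classification, an entropy-TOPSIS comparator, and global/local Moran's I
spatial analysis.

## The projection-pursuit model

After standardization every indicator lies in $[0,1]$ with "larger is
better" orientation.  For an observation matrix $x_{ij}$ ($i = 1..m$
observations, $j = 1..n$ variables) and a unit direction $a$, the projected
value of observation $i$ is

$$y_i = \sum_j a_j x_{ij}, \qquad \sum_j a_j^2 = 1 .$$

The projection index rewards directions along which the projected cloud is
both globally dispersed and locally clumped:

$$F(a) = S_y \cdot D_y, \qquad
S_y = \sqrt{\tfrac{1}{m-1}\sum_i (y_i - \bar y)^2}, \qquad
D_y = \sum_{i \ne k} (R - r_{ik})\, u(R - r_{ik}),$$

with $r_{ik} = |y_i - y_k|$ the one-dimensional projected distance, $u$ the
unit step, and $R$ a density window.  The direction maximizing $F$ exposes
the dominant clustering structure of the panel.

The model is run in two orientations:

* **indicator orientation** (`index_weights()`): the transposed matrix is
  the observation set, so each indicator is a point in region space; the
  optimal projection value of an indicator measures how much discriminating
  structure it carries, and these values — raw, and normalized to sum to
  one — are the indicator weights;
* **region orientation** (`resilience_scores()`): regions are observations
  and the optimal projection values are the composite resilience scores.
  `dimension_scores()` restricts the columns to one dimension.

The composite score is *not* the weighted mean of the four dimension scores;
`measure_resilience()` reports both and their gap, because each optimization
finds its own structure.  That non-additivity is a property of the method,
not an error, and distinguishes it from linear aggregators such as
entropy-TOPSIS (provided as `entropy_topsis()` for comparison).

### Choices the index definition leaves open

Three pieces of the density term are conventions rather than theorems, and
all are exposed as arguments of `projection_objective()`:

* **window radius** — default `R = 0.1 * S_y` (`fraction_of_spread`), the
  common convention in the projection-pursuit weighting literature; a fixed
  radius is available.  Tying $R$ to $S_y$ makes the objective
  scale-coherent across directions.
* **distance** — absolute difference of projected values; in one dimension
  no other natural choice exists.
* **self-pairs** — excluded by default.  Each self-pair contributes exactly
  $R$, which under the fraction rule varies with $a$ and inflates the
  objective by $m \cdot 0.1 \cdot S_y$ for every direction, distorting the
  comparison between directions.  A switch restores them.

The unit-norm constraint is enforced by renormalizing candidate directions
before evaluation, not by penalty, so every evaluated point is exactly
feasible.  Direction genes live in $[0,1]$ per component before
renormalization, which yields nonnegative, directly interpretable weights;
signed bounds can be supplied through `ga_config(bounds = ...)`.

## The optimizer

`raga_optimize()` is a real-coded GA on $[0,1]$ genes with the classic
accelerating cycle:

1. rank individuals best-first and give rank $i$ the geometric fitness
   $\alpha(1-\alpha)^{i-1}$ (default $\alpha = 0.05$);
2. roulette-select $N$ parents on the cumulative fitness sums;
3. arithmetic per-gene blend crossover (parents join the pool with
   probability $P_c$), directional mutation $z + M\,d$ with $M$ uniform on
   $(0,1)$ and $d$ uniform on the unit sphere, coordinates clamped to the
   box;
4. pool parents, offspring, mutants and the best-so-far point; the best $N$
   distinct individuals survive (elitist truncation, so the best objective
   is non-decreasing);
5. every `acceleration_period` generations (default 20) the per-variable
   bounds contract to the envelope of the elites archived over the whole
   period, and the cycle restarts with a fresh uniform population inside
   the shrunken box.

Two details matter in practice and are deliberate.  The acceleration
envelope spans the *archive* of each generation's elites rather than the
final generation only: truncation selection clusters the population within
a few generations, and an envelope taken from that cluster can lock the
optimum out of the box permanently.  For the same reason the restart after
each acceleration re-seeds diversity inside the new bounds.  With both in
place the optimizer recovers a 1-D quadratic optimum to ~1e-9 and a 3-D
sphere optimum to ~1e-3 per coordinate across seeds (the test suite checks
1e-3 / 1e-2); with neither, both targets fail by orders of magnitude.

Population size defaults to $N = 40$, $P_c = 0.8$, $P_m = 0.2$, matching
the configuration used for the indicator-orientation run; the region run
and the four dimension runs default to the published generation schedules
(100; and 15 / 200 / 400 / 150 respectively), all plain configuration.
A run stops early once the best objective improves by less than 1e-10 over
20 generations.  On a default synthetic 17x27 panel the region-orientation
objective plateaus well before a 2000-generation cap (typically below
1000), mirroring the convergence behaviour expected of the method;
`ga_config(max_iterations =)` controls the cap.

Everything is reproducible: a `ga_config(seed =)` fixes the whole
trajectory, and `run_pipeline()` fans one root seed out to per-stage seeds
so stages can be rerun in isolation.

## Preprocessing

`standardize()` applies the two-branch min-max map: positive indicators
$(x - \min)/(\max - \min)$, negative indicators $(\max - x)/(\max - \min)$.
A constant column has no range and is an error by default (`"drop"`
downgrades it to a warning).

`impute()` handles sparse missing cells with a noisy predictive fill: the
incomplete column is regressed on the fully observed columns by least
squares, the fitted value at a missing row is perturbed with Gaussian noise
scaled by `noise_scale` times the residual standard deviation,
`n_candidates` (default 5) draws are made, and one value is kept —
`closest_to_mean` (default) or the pooled mean.  The underlying procedure
description names no model or selection rule; ordinary least squares with
Gaussian noise is the simplest mechanism with all the stated properties
(predictive, noisy, multi-candidate, rule-selected), and the defaults are
documented as package choices, not as reconstructions.  Observed cells are
never touched, and `noise_scale = 0` collapses to the deterministic
regression prediction.  Cells are assumed missing at random.

## Classification

`jenks_breaks()` computes exact natural breaks by dynamic programming over
the sorted values (prefix-sum SSE, global optimum — verified against
exhaustive partition enumeration in the tests), with goodness-of-variance
fit $1 - SSE_{within}/SSE_{total}$.  Levels are numbered 1 = highest class,
and `assign_levels()` uses the convention of published five-level tables:
level 1 is `value >= top break`, interior classes are left-closed
right-open going downward, the bottom class is `value < lowest break`.

## Spatial analysis

`spatial_weights()` builds inverse-distance weights ($w_{ij} = 1/d_{ij}^p$,
default $p = 1$) from point coordinates, with a cutoff defaulting to the
smallest distance that leaves no region neighbourless; distance-band and
k-nearest-neighbour weights are available, and row standardization is
optional (off by default, since the global statistic carries its own
$\sum_{ij} w_{ij}$ normalizer).

`global_moran()` computes

$$I = \frac{n}{\sum_{ij} w_{ij}} \cdot
\frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2},$$

with expectation $-1/(n-1)$ — always reported signed; reports that print
the magnitude drop the sign — and a z-score from the standard
$S_0/S_1/S_2$ moment formulas under either the randomization null (default,
the convention of common GIS reports) or the normality null.  The two
variances agree only asymptotically at Gaussian kurtosis; the gap is
$O(1/n^2)$, which the tests verify rather than asserting exact equality.
`moran_permutation_test()` supplies a distribution-free pseudo p-value that
is reported alongside, never silently substituted.

`local_moran()` gives the per-region decomposition $I_i$ (satisfying
$\sum_i I_i = S_0 \cdot I$), LISA quadrants HH/LL/HL/LH from the signs of
the deviation and the spatial lag, and conditional-permutation pseudo
p-values.  For subgroup readings (e.g. an east/west split)
`subset_moran()` restricts and re-standardizes the weights and reports
*both* the subset's global I and the mean of its local I, labelled — a
single per-group number is ambiguous between the two conventions, so both
are emitted.

The textbook claim that $I \in [-1, 1]$ is only approximate;
`moran_bounds()` reports the exact attainable range from the spectrum of
the doubly centered symmetrized weight matrix.

## The synthetic generator

`make_panel()` emulates the study conditions the package targets: 17
regions, 27 indicators laid out 7/8/6/6 over the four dimensions, the
population-density/major-disaster/economic-loss style indicators negative,
scale families cycling through counts, percentages and 10^4-Yuan monetary
magnitudes so standardization is exercised over heterogeneous units.
Latent per-dimension factors are drawn with spatial structure via a
simultaneous-autoregressive (SAR) transform
$x = (I - \rho W)^{-1}\varepsilon$ on row-standardized inverse-distance
weights over random planar coordinates; SAR was chosen because one
parameter spans the negative/null/positive Moran regimes a real province
can exhibit.  Defaults: `spatial_rho = 0.5` (moderate clustering),
`latent_dimension_strength = 1` (indicators split their variance roughly
evenly between their dimension factor and idiosyncratic noise), and
`missing_rate = 0.013` — about six missing cells in a 17x27 panel, the
sparse-gap regime the imputation stage is designed for, masked at most one
per column.

What the generator does *not* emulate: real indicator distributions are
often skewed and bounded in ways a Gaussian latent model is not; real
missingness can be structural rather than random; and real administrative
units have polygon adjacency rather than point geometry.  Tests passing on
synthetic panels certify the algorithms' contracts, not the substantive
conclusions one would draw from any particular real panel.

`known_optimum_problem()` supplies certified test problems: a 1-D quadratic
and an n-D sphere with known argmax for the optimizer, and a
planted-dominant-indicator panel — one bimodal indicator against
near-constant noise — for the weighting stage.  That bundle exposes its
values directly as a standardized panel, since re-standardizing would
stretch the noise columns to full range and erase the planted contrast.

## Numerical choices and degenerate inputs

* Rank fitness uses exponent $i - 1$ so that better ranks receive larger
  fitness; replication probability is then proportional to fitness, as the
  selection scheme requires.
* Survivor truncation keeps the best $N$ with *distinct* genes preferred,
  preventing envelope collapse (see above); ties in ranking break by
  stable input order.
* A collapsed acceleration interval is re-widened symmetrically by 1e-6 of
  the original span so the variable stays searchable.
* Zero direction vectors are rejected; matrices with identical rows give
  $S_y = 0$ and hence $F = 0$ for every direction, which the measurement
  layer surfaces as a zero objective rather than an error.
* A pair exactly at the window edge ($r = R$) contributes zero weight, so
  the density is continuous in $R$.
* Constant score vectors are rejected by every Moran routine (zero
  variance), coincident points are rejected by inverse-distance weights
  (infinite weight), and `jenks_breaks()` requires at least as many
  distinct values as classes.

## Problem sizes used by the tests and the acceptance script

Oracle-equivalence checks run at $n \le 8$ (Moran), $m \le 12$ (Jenks
enumeration) and 5x3 direction grids (projection index), where brute force
is exact and instant.  Statistical calibration uses 200 SAR replicates on a
7x7 grid with 999 permutations each; optimizer recovery uses 10 seeds per
problem.  The end-to-end runs use the default 17x27 synthetic panel.  These
sizes were chosen to make every check exact or tightly bounded while
keeping a full run of the suite in well under a minute of compute.

## Known limitations

* The GA is stochastic; two different seeds give slightly different optimal
  directions (scores typically agree to ~1e-3 relative once converged).
  All entry points therefore require or derive explicit seeds.
* Weights are defined as indicator-orientation projection values (the
  framework's own convention), not as the components of the optimal
  direction; `index_weights()` returns the direction too for users who
  prefer the latter.
* Point-distance weights only; polygon contiguity is out of scope.
* The imputation model is a single-equation OLS fill, not chained
  equations or a full posterior; it is aimed at a handful of scattered
  gaps, not systematically missing blocks.
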