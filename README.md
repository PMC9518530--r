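# resilpp

Composite regional resilience indices by projection pursuit, with an
accelerating genetic algorithm, natural-breaks classification and spatial
autocorrelation analysis.

## The problem

Emergency-management analysts evaluating how resilient a set of regions is
to compound disasters face a small, wide panel: a handful of regions (say a
province's 17 sub-provincial units), dozens of indicators in mixed units
(counts, percentages, monetary stocks), some indicators "more is better"
and some "more is worse", and a few missing cells.  They need indicator
weights that come from the data rather than from expert scoring, one
composite score per region plus per-dimension scores, a defensible
grouping of regions into levels, and a reading of whether high- and
low-resilience regions cluster in space.

`resilpp` is that toolchain for R.

## The model

After orientation-aware min-max standardization, a unit direction
$a$ ($\sum_j a_j^2 = 1$) projects the observation matrix to
$y_i = \sum_j a_j x_{ij}$, and the projection index

$$F(a) = S_y \cdot D_y,\qquad
S_y = \sqrt{\tfrac{1}{m-1}\sum_i(y_i-\bar y)^2},\qquad
D_y = \sum_{i\neq k}(R - r_{ik})\,u(R - r_{ik})$$

scores the direction by global spread times windowed local density
($r_{ik} = |y_i - y_k|$, default window $R = 0.1\,S_y$).  Maximizing
$F$ with a real-coded accelerating genetic algorithm (RAGA) — rank-based
geometric fitness, roulette selection, arithmetic crossover, directional
mutation, and periodic shrinking of the search box around archived
elites — yields:

* **indicator weights**: optimal projection values with indicators as
  observations (transposed matrix), also normalized to sum to one;
* **region scores**: optimal projection values with regions as
  observations, overall and per dimension.

Scores are then classified into five levels with exact Jenks natural
breaks, compared against an entropy-TOPSIS baseline, and analyzed
spatially with global Moran's I (randomization or normality inference plus
permutation tests) and local Moran's I with HH/LL/HL/LH quadrants.

## Worked example

```r
library(resilpp)

sp  <- make_panel(synthetic_spec(seed = 5))   # 17 x 27 synthetic panel + coordinates
print(sp$panel)
res <- run_pipeline(sp$panel, sp$coords, seed = 11)
print(res$measure)
print(res$moran)
head(res$local$table, 4)
```

```
indicator_panel: 17 regions x 27 indicators, 8 missing cell(s)
dimensions: resistance=7, restore=8, adaptability=6, collaborative=6
measure_report: 17 regions, 27 indicators
objective (region orientation): 0.98308
Jenks 5-level breaks: 2.148, 2.327, 2.9, 3.267 (gvf 0.997)
mean |score - dimension weighted mean| = 1.272
global Moran's I: -0.145022
expected: -0.062500
variance (randomization): 0.032182
z-score: -0.460004
p-value: 0.645513
    label       I_i  deviation       lag quadrant pseudo_p
R01   R01 14.439477 -0.3794139 -7.612701       LL    0.311
R02   R02 -2.355844  0.3965889 -1.188247       HL    0.735
R03   R03 -1.938735 -0.3819535  1.015333       LH    0.827
R04   R04 14.525584 -0.3791189 -7.664056       LL    0.400
```

Reading the output: the pipeline imputed the 8 missing cells, standardized
the panel, ran the genetic optimizer in both orientations, and cut the 17
region scores into five levels whose breaks explain 99.7% of the score
variance (`gvf`).  The mean absolute gap of 1.272 between the composite
score and the weighted mean of the four dimension scores shows the
method's non-additivity — the composite is not a linear roll-up of its
dimensions.  Global Moran's I of −0.145 against an expectation of −0.0625
(z = −0.46, p = 0.65) says this particular synthetic province shows no
significant spatial clustering of resilience; the LISA table classifies
each region's local association (e.g. R01 sits in a low-low cluster, R02
is a high value among low neighbours).

The full measurement detail lives in the result: `res$measure$weights`
(per-indicator projection values and normalized weights),
`res$measure$scores`, `res$measure$dimension_scores`,
`res$measure$classification`, `res$measure$comparator` (entropy-TOPSIS),
and `res$manifest` (seeds, config, stage log).

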