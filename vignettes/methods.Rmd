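---
title: "Monitoring screening participation across space and time: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring screening participation across space and time: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stscreen)
library(data.table)
```

Organized cancer-screening programs mail invitations to every eligible
woman on a fixed cycle, and the fraction who attend varies across
neighborhoods and drifts over the years. `stscreen` turns a table of
georeferenced invitations into (i) stabilized small-area participation
rates, (ii) a map of statistically significant participation clusters,
(iii) a trajectory label per neighborhood describing how its clustering
state evolved, and (iv) an interpretable model of area-level determinants.
A synthetic-canton generator with planted space-time structure provides
ground truth against which every stage is validated.

This vignette explains the statistical machinery, the parameters that
matter, the design decisions that were genuinely open, and what the
validation results do and do not establish.

## From invitations to a neighborhood panel

Invitations carry a date, a participation flag (0/1), an age group and a
location. Records are pooled into **biennial periods** labeled by the even
year (2003 and 2004 both become "2004"), matching a two-year invitation
cycle; `assign_period()` excludes and counts records outside the study
window. Points are assigned to the neighborhood polygon containing them;
points outside every polygon go to the nearest polygon by boundary
distance, and points exactly on shared boundaries are assigned uniformly
at random under a fixed seed so repeated runs agree.

The raw rate in neighborhood $i$ and period $t$ is
$r_{it} = 100\, o_{it} / n_{it}$ (participants over invitations). Cells
with no invitations are *missing*, never zero.

## Spatial empirical Bayes smoothing

Small denominators make raw rates jumpy, so rates are shrunk toward a
local reference before any cluster statistic sees them. For each cell the
window $J_i$ is the cell plus its $k = 8$ nearest neighbors (centroid
distance, rebuilt among the units observed in that period). With window
rate $m_i = \sum_{J_i} o_j / \sum_{J_i} n_j$ the local variance estimate
is

$$v_i = \frac{\sum_{J_i} n_j (r_j - m_i)^2}{\sum_{J_i} n_j}
        - \frac{m_i}{\sum_{J_i} n_j / |J_i|},$$

floored at zero, and the smoothed proportion is
$\theta_i = m_i + w_i (r_i - m_i)$ with shrinkage weight
$w_i = v_i / (v_i + m_i / n_i)$, reported $\times 100$. Two properties are
enforced by construction and tested: $\theta_i$ always lies between $r_i$
and $m_i$, and for fixed window moments $w_i$ grows with $n_i$ (rich cells
barely move, thin cells borrow strength). When the window shows no
extra-binomial variance ($v_i = 0$) the cell collapses fully to the window
rate — the variance floor is the standard choice that keeps $\theta$ in
range. The exact moment formulas above are pinned in this package and
unit-tested against their own closed form, so results do not drift with
external library versions.

## Hot and cold spots: the local Gi* statistic

Participation clusters are found with the Getis–Ord Gi\* statistic under
binary $k$-nearest-neighbor weights on neighborhood centroids
(self-included "star" form, $W = k+1$):

$$z_i = \frac{\sum_j w_{ij} x_j - \bar{X} W}
             {S \sqrt{\left(n W - W^2\right)/(n-1)}},$$

with $\bar X$ and $S$ the global mean and (population) standard deviation.
KNN weights are used because irregular urban neighborhoods often lack
enough contiguous neighbors, and equal neighbor counts make binary weights
row-balanced without standardization. $k = 16$ is the reported default;
$k = 8$ is available.

Significance uses **conditional Monte-Carlo permutation** (default 9999
draws): the focal value stays fixed while the $k$ neighbor values are
drawn without replacement from the remaining $n-1$ values. The pseudo-p is
$(m+1)/(B+1)$ where $m$ counts permutations with $|z| \ge |z_{obs}|$; the
*sign* of the observed $z$ decides hot versus cold, while the p-value is
two-sided on the magnitude. This convention keeps the test at its nominal
level — measured rejection at $p < 0.05$ over exchangeable surfaces is
within the 0.04–0.06 band — whereas counting only the observed direction
doubles the type-I rate. Results are reported in graduated classes at
$p < 0.001, 0.01, 0.05, 0.1$. Zero-variance surfaces return a flagged
degenerate result rather than z-scores.

The permutation draw scheme is pinned (units in index order, a $k$-step
partial Fisher–Yates consuming one R uniform per step), so the compiled
implementation and a plain-R reference implementation produce *identical*
pseudo-p vectors under a shared seed while computing the statistic through
different code paths.

## Emerging hot spot analysis

The space-time view stacks the smoothed panel into a cube of location
$\times$ period bins (missing cells masked, never imputed; a 2121-location,
9-period panel has 19,089 bins). Each bin gets a Gi\* score whose
neighborhood is the bin itself plus the spatial KNN ($k = 16$) of its
location at temporal lags $-1, 0, +1$; masked bins drop out of the sums
with the weight count renormalized. The global mean, SD and $n$ are taken
over all observed bins. Bin p-values are two-sided normal and corrected
across all bins jointly by Benjamini–Hochberg FDR at $\alpha = 0.05$; a
rejected bin is *hot* ($z > 0$) or *cold* ($z < 0$), otherwise *neither*.

Each location's trend is the Mann–Kendall test applied to its series of
bin z-scores (intensity), not raw rates — the trajectory vocabulary below
speaks of changes in cluster *intensity*, and intensity is what the
z-score measures. With $S = \sum_{i<j} \mathrm{sgn}(x_j - x_i)$ and
tie-corrected variance
$\mathrm{Var}(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18$, the
continuity-corrected $z = (S \mp 1)/\sqrt{\mathrm{Var}(S)}$ gives a
two-sided p; the direction call uses $\alpha_{trend} = 0.05$.

Finally each location's hot/cold indicator string and trend are classified
into one of **17 trajectory categories** (1 no-pattern + 8 hot + 8 cold):
new, consecutive, intensifying, persistent, diminishing, sporadic,
oscillating and historical, for each family. The hot rules are evaluated
in a fixed order; the mirrored cold rules run only when no hot rule fires:

1. **New** — hot in the final period, never hot before.
2. **Consecutive** — an uninterrupted final run of ≥ 2 hot periods with no
   earlier hot period, and < 90% of periods hot.
3. **Intensifying / Persistent / Diminishing** — hot in ≥ 90% of periods
   with an increasing / absent / decreasing intensity trend.
4. **Sporadic** — hot in the final period, < 90% hot, no cold periods.
5. **Oscillating** — hot in the final period, < 90% hot, at least one
   prior cold period.
6. **Historical** — *not* hot in the final period but hot in at least
   **50%** of periods. The 50% threshold (rather than the conventional
   90%) deliberately widens this class to capture meaningful erosion of
   formerly engaged areas.

For the cold family the trend direction is mirrored: a cold spot
*intensifies* as its z-scores grow more negative, so intensifying-cold
pairs with a decreasing trend. Locations observed in fewer than two
periods are labeled no-pattern and flagged. The classifier is validated by
exhaustive enumeration: all $3^9$ indicator strings crossed with the three
trend states match an independently coded rule table on every input, and
exactly one label fires per input.

## Accessibility to screening centers

Physical access is a linear-decay density over street-network distances:
from each query point, every active center at shortest-path distance
$d \le 5000$ m contributes $1 - d/5000$, and centers beyond the radius (or
unreachable) contribute zero. The 5 km radius reflects local travel in a
dense urban context; the linear decay privileges closer centers. Center
openings and closures gate the contribution per period. Query points and
centers snap to their nearest network node (ties to the smallest node id);
the Euclidean snap leg is ignored by default and can be added with
`add_snap_leg = TRUE`. The raw decayed sum is reported without
normalization — documented so users can rescale if desired. Individual
addresses and neighborhood centroids are both supported as query points;
the modeling stage uses centroids.

## Determinants model

The final-period smoothed rate is regressed on the deprivation index, the
center-density access score, the five age-group shares of invited women
and the centroid coordinates, using gradient-boosted trees (xgboost). The
80/20 train/test split is seeded and recorded. Hyperparameters (tree
depth 2–8, learning rate 0.01–0.3 log-scaled, row and column subsampling
0.5–1, minimum child weight 1–10 log-scaled, gamma 0–5) minimize 5-fold
cross-validated RMSE through Bayesian optimization: a Latin-hypercube
initial design, a Gaussian-process surrogate, and expected-improvement
proposals. The final model trains with early stopping on a 10% carve-out
of the training rows, and test metrics are computed once on the untouched
20%.

Interpretation uses exact tree-path Shapley attributions
(`predcontrib`/`predinteraction`): per-row local accuracy (attributions
plus base value reproduce the prediction to the booster's float32 storage
precision, about $10^{-4}$ at the percent scale), mean-|attribution|
importance ranking, and pairwise interaction strengths on a row
subsample. The smoothed rate is the default outcome — mirroring the
analytical panel — with the caveat that smoothing itself injects spatial
structure, so the weight of the coordinate features should be read
cautiously; `outcome = "raw_rate"` supports sensitivity runs.

## The synthetic canton: what it emulates, and what it does not

`canton_spec()` defines the reference study conditions used by the
validation suite:

| parameter | default | why |
|---|---|---|
| neighborhoods | 400 Voronoi cells in a 10 km square | irregular, contiguity-poor units (the motivation for KNN weights) at a tractable scale |
| periods | 9 biennial labels, 2004–2020 | one full program horizon |
| cohort | 60,000 women, ages 48–74 uniform at start | ages straddle the 50–74 eligibility window so cohort turnover occurs; ~100+ invitations per cell per period |
| deprivation field | Gaussian-kernel-smoothed white noise, scale 1500 m, min-max to [0,1] | spatially autocorrelated index, higher = more deprived |
| baseline | intercept `qlogis(0.4)` | ~40% background participation |
| covariate effects | +0.15 (deprivation), −0.02 (access) log-odds | present but deliberately below cluster-detection scale (see below) |
| overdispersion | neighborhood-period sd 0.5 log-odds (transient); persistent sd 0 | see below |
| planted patterns | persistent hot, intensifying hot, persistent cold, intensifying cold; 20-unit cores, peak ±0.8 log-odds, 16-unit half-shift halos | balanced, recoverable ground truth |
| centers | 12, clustered in the urban core, staggered activity | openings/closures exercise the access panel |
| network | jittered 31×31 grid, Euclidean edge lengths | simple, reproducible shortest paths |
| registry | ~15–40 buildings per neighborhood, French-style street names, ~16 postal zones | geocoder benchmarks with known truth |

All randomness flows from one master seed through documented stream
splitting (`derive_seed()`), so two runs with equal specs are
byte-identical.

Four design points deserve their reasoning spelled out, because each was
forced by a real interaction between the generator and the statistics:

* **Transient, not persistent, overdispersion.** The empirical-Bayes
  smoother only stays adaptive when windows contain genuine
  extra-binomial variance; under pure binomial noise it collapses every
  cell to a moving average whose induced spatial correlation makes bin
  Gi\* anti-conservative everywhere. Neighborhood-*period* fluctuations
  (campaign timing, local events; sd 0.5) supply that variance without
  correlating a location's bins over time. A *time-constant* neighborhood
  effect would make every location's bins dependent across periods, and
  emerging-hot-spot analysis then legitimately categorizes much of the
  map — as real analyses of real panels do. That knob
  (`sd_neighborhood`) therefore defaults to 0 and exists for sensitivity
  runs; with it on, "background flagged" is no longer a meaningful error
  rate.
* **Balanced planting.** Hot and cold planted mass are equal, because the
  global cube mean is the Gi\* reference: planting only hot regions shifts
  the mean up and the entire background reads as cold.
* **Tapered halos.** Each core is wrapped in a 16-unit halo at half
  shift. Real participation clusters fade over space rather than ending
  at a cliff, and a $k = 16$ local statistic integrates over exactly such
  a one-shell margin: halo units are genuinely shifted, so they belong to
  the planted cluster's footprint and count neither as recovery cores nor
  as background.
* **Moderate core shifts.** ±0.8 log-odds (roughly 40% → 59%) rather
  than larger values: the detection ring around a cluster *grows* with
  the planted amplitude relative to the background noise floor, so
  moderate shifts keep the cluster footprint tight while remaining far
  above the detection threshold.

What the generator does **not** emulate: residential mobility (women stay
in one neighborhood; real programs track person-neighborhood
observations), opportunistic screening outside the program, realistic
demography or migration, and any persistent unmeasured heterogeneity by
default. Passing the planted-recovery checks therefore shows the chain
detects and labels clusters of the planted kind under calibrated noise —
it does not promise that a real canton's category map has a ≤10% false
rate, because real backgrounds contain exactly the persistent
heterogeneity the default generator omits.

## The offline geocoder

Address strings are normalized (lowercase, diacritics and punctuation
stripped, street-type abbreviations expanded from a documented extensible
dictionary, the trailing digit token extracted as the street number) and
matched against a building registry by the Ratcliff–Obershelp ratio
$2M/(|a|+|b|)$, computed on the street name without the number. A quick
pass searches the address's postal code; below the 0.80 acceptance
threshold a slow pass searches the whole registry. A matched street
without a usable number returns the street centroid. Ties prefer the
address's postal code, then the lexicographically smallest registry key.
No network calls are made anywhere. Instead of interactive cleaning near
the threshold, `review_band()` exports matches with similarity in
[0.75, 0.85] for manual review. Raising the threshold can only move
matches toward failure, never rescue them — a monotonicity property under
test.

## Numerical choices and degenerate inputs

* Negative local variance in the smoother floors at 0 (full shrinkage).
* Zero-variance surfaces: Gi\* returns a flagged degenerate result; the
  cube classifier emits all-neither indicators, hence no-pattern labels.
* Pseudo-p uses $(m+1)/(B+1)$, so p is never 0.
* Constant or short (< 4 observed values) series get Mann–Kendall
  direction "none".
* KNN distance ties break by unit order; node-snap ties by smallest id;
  boundary-assignment ties by seeded uniform choice.
* Empty cells are missing, not zero, at every stage; conservation of
  invitation counts through aggregation is asserted exactly.

## Problem sizes used in validation

The test suite and the acceptance script run: the reference canton (400
neighborhoods × 9 periods, 60,000 women) through the full chain;
permutation calibration on 200 exchangeable 400-unit surfaces at 999
permutations; exhaustive classifier enumeration ($3^9 \times 3$ cases);
brute-force oracle comparison on 100-unit surfaces; 1000 random panels
for smoothing properties; a 5000-entry registry with 400 perturbed
addresses; and a 2000-row determinants recovery. These sizes were chosen
so the whole validation cycle completes in minutes on a laptop while
leaving every statistical conclusion at conventional precision.

## Known limitations

Age-standardized rates and covariate adjustment at the panel stage are
out of scope, as are gravity/two-step-floating-catchment access models,
multi-modal travel times, and causal reading of the determinants model.
The EHSA category map inherits the smoothing caveat: SEBS reinforces
spatial organization, which is partly why smoothed panels categorize more
of the map than raw ones. The five ESRI category variants beyond the 17
listed here are intentionally not implemented.
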