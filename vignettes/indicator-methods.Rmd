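---
title: "Community regime-shift indicators: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community regime-shift indicators: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trawlshift)
```

`trawlshift` computes a suite of community-level indicators from
multi-species bottom-trawl surveys, designed around the analysis of the
Newfoundland-shelf groundfish collapse and recovery. This vignette explains
each indicator's model and assumptions, the tunable parameters and their
defaults, the numerical choices made where the design was genuinely open,
and what the synthetic-survey validation does and does not demonstrate.

## The biomass estimator

Trawl catches of a given species are zero-inflated (many tows catch none)
and approximately lognormal when positive. The average biomass per tow is
therefore estimated as the geometric mean of the positive catches, scaled by
the fraction of tows that are positive:

$$E_{\mathrm{zinf\text{-}G}} = \frac{m}{n}
  \exp\!\Big(\frac{1}{m}\sum_{i=1}^{m}\ln b_i\Big),$$

with $n$ tows in the group (a survey year, or a polygon-year), $m$ of them
positive, and $b_i$ the positive catches (kg/tow); the estimate is 0 when
$m = 0$. This is the delta-geometric-mean estimator familiar from trawl
survey analysis: robust to the extreme catches that dominate an arithmetic
mean, while still tracking both occupancy ($m/n$) and local density (the
geometric mean). It estimates a *relative* index, not absolute abundance —
all downstream indicators use it comparatively across years or polygons.

Standard errors use the leave-one-out jackknife with the trawl (the sampling
unit) as the resampling unit:
$SE = \sqrt{\tfrac{n-1}{n}\sum_i (\theta_{(i)} - \bar\theta)^2}$. For the
arithmetic mean this reduces exactly to $sd/\sqrt n$, which the test suite
uses as a closed-form oracle. A group absence (species never caught) is an
explicit zero at matrix-construction time: the estimator must see `n` as
*all* trawls of the group, so community matrices are built from the full
trawl roster, not just the recorded positive catches.

### Gear-change screening

A mid-series gear change (1995 in the default configuration) increases the
catchability of small-bodied species and can masquerade as recovery. Before
any analysis, two screening rules remove species whose index cannot be
compared across the change: species captured in fewer than `min_pre_trawls`
pre-change trawls (default 1, i.e. only never-captured species — the
boundary is configurable because "captured infrequently" admits no unique
count), and species whose post-change-window mean (default 1995–2000)
exceeds `gear_ratio_threshold` (default 7, strict inequality) times the
pre-change mean. Era means pool all trawls of an era through the estimator
above rather than averaging annual means, because the screening ratio is a
statement about eras, not about years. Matched-trawl conversion factors
(`gear_conversion_factors()`, a one-way random-effects shrinkage of
per-species mean log catch ratios toward the across-species grand mean,
with species under 3 pairs inheriting the grand mean) are provided but OFF
by default: the screened, untransformed series are the primary analysis.

## Community synchrony

The variance-ratio statistic
$\varphi = \operatorname{var}(\sum_s x_s) / (\sum_s \mathrm{sd}\,x_s)^2$
(population-variance convention, matching the statistic's source
definition) is 1 when species fluctuate proportionally and 0 when
fluctuations cancel. It is abundance-weighted: rescaling one species'
series changes φ, by design; adding an all-zero species or relabeling
species does not. φ is computed in a running window (default 5 years)
ending in each year, so the indicator is attributable to a specific period.

Significance uses a one-sided Monte-Carlo test: each species' values are
permuted independently within the window (destroying cross-species
alignment while preserving every marginal exactly), `n_randomizations`
(default 999) times, and $p = (1 + \#\{\varphi_{null} \ge
\varphi_{obs}\})/(R+1)$ — the add-one rule keeps p-values positive and the
test exact. With 5-point windows only $5!^{S}$ rearrangements exist, but
with tens of species the permutation space is ample; phase randomization
and other nulls were not implemented because they are not meaningful at
this window length. Windows straddling the gear change are flagged rather
than dropped. Each window is classified *increasing* or *declining* by the
sign of the least-squares slope of the community total within the window —
a deliberate, simple operationalization of "direction of change".

The type-I error of this test at α = 0.05 is verified by simulation
(200 null communities) in the test suite.

## Compositional trajectories

Annual compositions are relative biomasses (rows of the year × species
estimate matrix normalized to sum 1). Dissimilarity is Bray–Curtis,
$BC(x,y) = \sum_s |x_s-y_s| / \sum_s (x_s+y_s)$, via `vegan::vegdist`; the
quantitative Sørensen similarity is its complement.

### NMDS

Two-dimensional non-metric MDS minimizes Kruskal's stress-1 with SMACOF
majorization alternated with isotonic regression (`stats::isoreg`) of
configuration distances on the dissimilarity order (weak/primary tie rule:
tied dissimilarities may untie in the direction of the current distances).
A Guttman step that would increase stress is replaced by backtracking
halfway toward the previous configuration, so the reported per-iteration
stress sequence is provably non-increasing — a property the tests assert on
every input. Defaults: 20 random starts plus one classical-scaling start,
300 iterations, convergence at relative stress change `1e-7`. Coordinates
are centred and rotated to principal axes, but remain identifiable only up
to rotation/reflection; downstream consumers use distances and stress, and
the tests compare seeded runs by Procrustes distance, never raw axes. No
Wisconsin or square-root pre-transformation is applied: the input is
already relative biomass.

### Relative-change scaling

Recovery series are rescaled as
$s_t = 100\,(x_t - \min x)/(x_{ref} - \min x)$, anchoring 0 at the maximum
observed departure and 100 at the reference year (default 1981). The anchor
form is used because it is the only scaling consistent with both anchors
simultaneously; it is invariant to positive affine transformations of the
input, and errors out when the reference value *is* the minimum (the scale
is undefined there). A value above 100 means the indicator has overshot its
reference level.

## Functional diversity

Six traits enter a Gower dissimilarity: body length, population doubling
time and trophic level as numerics (range-normalized absolute differences),
vertical position, aggregation and food niche as unordered categoricals
(0/1 mismatch), averaged with equal weight. Doubling time and trophic level
are treated as numeric because they are continuous indices in their source
databases. Ranges are computed once over the full species pool — not per
year and not per subset — so dispersion values are comparable across years
and between the whole-community and non-commercial series. A zero-range
numeric trait is uninformative and dropped with a warning.

Gower matrices are generally non-Euclidean, so species are embedded by
principal-coordinates analysis; when negative eigenvalue mass exceeds
`1e-8` of the total, the Cailliez correction (the smallest additive
constant making the off-diagonal distances Euclidean, found as the largest
eigenvalue of the standard 2n × 2n companion problem) is applied —
Cailliez rather than Lingoes, matching common FDis practice. The embedding
is verified to reproduce the corrected distances to `1e-8`.

FDis is the abundance-weighted mean distance to the abundance-weighted
centroid: $c = \sum_j a_j x_j / \sum a_j$,
$\mathrm{FDis} = \sum_j a_j \lVert x_j - c\rVert / \sum a_j$, with annual
relative biomasses as weights. It is zero iff all weight rests on
coincident species, and invariant to weight rescaling, rigid rotations and
zero-weight species — all tested, alongside an exact brute-force oracle.

## Spatial structure

Trawls are aggregated into a planar partition of the survey domain. The
cells are plain Voronoi polygons built by half-plane intersection from
configurable seed points (defaults to k-means centroids of the trawl
locations, k = 150, when no polygon file is supplied); mesh-based
constructions tied to particular spatial-modelling software are
deliberately out of scope, as their constraints are descriptive rather than
reproducible. Each cell carries the arithmetic mean of observed trawl
depths. Point-in-polygon assignment uses `mgcv::in.out`, with boundary
points snapped to the lowest-id adjacent cell for determinism.

**Community types.** Polygon-period compositions (default periods
1981–84, 1985–89, 1990–94, 1995–2001, 2002–06, 2007–13 — breaks chosen to
avoid spanning the collapse onset or the gear change) are clustered by
complete-linkage `hclust` on Bray–Curtis dissimilarity and cut into
`n_clusters` (default 7) groups. Labels are canonicalized by the descending
peak share of each cluster's mean composition, so they are stable under row
reordering; ties inside `hclust` follow its internal rule, which is
irrelevant for continuous dissimilarities. The merge tree is verified
against an O(n³) brute-force reference in the tests.

**Depth/distance variance partitioning.** For every polygon pair present in
a year: response `logit(BC)` (clamped to [1e-4, 1 − 1e-4]), predictors
`ln(|Δdepth| + 1e-3 m)` and `ln(great-circle distance + 1e-3 km)` (sphere
radius 6371.0088 km). Both predictors are log-transformed by default, with
per-predictor flags, since "logit and log transformations" leaves the
distance transform ambiguous. Reported are the adjusted R² of the
two-predictor model and partial adjusted R²s defined as adj R²(full) minus
adj R²(other predictor alone). Pairs are treated as independent
observations; no Mantel-type correction is attempted, so the R² values are
descriptive of linear distance-decay strength, not hypothesis tests. Only
polygons surveyed in at least `min_years_present` (default 30) of the 33
survey years enter, so trends in R² are not artefacts of changing spatial
coverage.

**Diversity diagnostics.** Alpha diversity is mean per-trawl species
richness (an explicit choice — the metric is otherwise unspecified in this
family of analyses); beta structure is the mean and variance of the
off-diagonal between-polygon Bray–Curtis values per year.

## Drivers

Fishing effort is Σ tonnage × days-at-sea over benthic-target vessels per
year (tonne-days). Climate components are z-scored over a 1981–2010
baseline, sign-aligned so negative = colder, and summed. Smoothing uses a
*trailing* window (ending in the year of interest), chosen for consistency
with the synchrony window, which is likewise anchored to its end year.

## The synthetic survey generator

`simulate_survey()` draws a survey whose statistical structure matches the
assumptions above, with the generating quantities exposed for recovery
tests:

* Regional log biomass: $\log B_{s,t} = \beta_s + \gamma_s D_t +
  \delta_{s,t}$, with $D_t$ a common driver accumulated from per-phase
  slopes and $\delta_{s,t} \sim N(0, 0.15)$ species-year noise.
* Space: 150 Voronoi cells on a lon/lat rectangle; cell depth = 100 m +
  400 m × latitude fraction + N(0, 30 m), clamped ≥ 30 m, so depth and
  geography are partially confounded as on a real shelf — without this the
  variance-partitioning stage would be degenerate.
* Local density: $B_{s,t}\exp(-(z_p-\mu_s)^2/2w_s^2)$ for cell depth
  $z_p$; presence ~ Bernoulli(logistic(1.5 · log density)); positive catch
  lognormal with median at the density (sd 0.8). Trawl counts per year are
  rounded N(421, 62), truncated at ≥ 50 — the sampling intensity of the
  motivating survey.
* Gear change: from 1995, density is multiplied by
  $\exp(k(\bar L - L_s)/\bar L)$ clamped to [1, 10] (default k = 0.8):
  smaller fish become more catchable, the direction real gear changes took,
  with an invented but monotone functional form.

`default_collapse_scenario()` fixes a four-phase history: stable 1981–86,
synchronous decline 1987–94 (slope −0.45/yr, all species loading
positively), shifted regime 1995–2004 (flat trough; the driver-insensitive
species `sp02` — deliberately placed at the trait-space centre — takes
dominance from the high-loading, large, schooling `sp01`), compositional
recovery 2005–09 (+0.2/yr) and biomass growth 2010–13 (+0.1/yr). The driver
ends at −2.2 of its −3.6 trough, so recovery is designed to be partial.
Ground truth includes the driver path, noiseless and realized expected log
biomasses, the estimator's large-sample target per species-year (mean
presence probability × presence-weighted geometric mean density over the
polygon pool), noiseless per-window synchrony, and the designed trough
years.

**What passing the recovery tests shows — and does not.** The generator
reproduces zero inflation, skewed catches, depth niches, gear bias and
common-driver regime phases, so the tests demonstrate that the pipeline
detects collapse, dominance shift, functional-dispersion loss and partial
recovery when they are present, at realistic survey effort, and stays quiet
in stable phases. It does not emulate species interactions, recruitment
dynamics, spatial population contraction, observation error in trawl
location/depth, or taxonomic drift — so passing says nothing about those
failure modes in real data, and the generator is not calibrated to any real
survey.

## Numerical choices and degenerate inputs

* All-zero community rows are excluded from dissimilarities with a warning
  and flagged by `normalize_rows()`; a single all-constant window makes φ
  undefined (`NA` with a `degenerate` attribute) rather than 0/0.
* The jackknife SE is `NA` with a warning for n < 2; the zero-inflated
  estimator errors on empty or negative input.
* NMDS backtracks rather than oscillates; coincident points in a
  configuration contribute zero to the Guttman transform.
* The relative-change scale errors when reference equals minimum; the
  pipeline skips such a series with a warning instead of aborting the run.
* Every randomized stage (simulation, permutation nulls, NMDS starts,
  k-means seeds) derives from a single integer seed and restores the
  caller's RNG state.

## Problem sizes used in validation

The shipped tests validate oracle properties on small instances (6–14
points for ordination and clustering oracles, 8-species FDis instances,
10-species null communities for the type-I simulation with 199 permutation
replicates and 200 repeats) and run the full default scenario (33 years ×
30 species × ~421 trawls/year) across 25 seeds for end-to-end recovery,
with 199-replicate synchrony tests in the designed collapse and stable
windows. `scripts/acceptance.R` runs one full pipeline (999 replicates) on
the default scenario. These sizes were chosen to exercise every code path
at the survey's native scale while keeping a complete validation run in the
minutes range on one core.

## Known limitations

* The pairwise regression in the variance partition ignores the dependence
  among pairs sharing a polygon; its R² values are comparable across years
  but are not significance-tested.
* The conversion-factor model assumes a caller-supplied trawl matching; no
  matching algorithm is provided.
* Bray–Curtis on estimator output inherits estimator noise; with very few
  trawls per polygon-year the dissimilarity mean/variance diagnostics are
  upward-biased.
* NMDS is a visualization device here; no significance is attached to
  ordination axes.
* The 7× screening rule and the never-captured rule are blunt instruments;
  sensitivity to `gear_ratio_threshold` and `min_pre_trawls` should be
  checked on real data.
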