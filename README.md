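# trawlshift

Community-level regime-shift indicators for multi-species bottom-trawl
surveys.

When an exploited fish community collapses and reorganizes — as the
Newfoundland-shelf groundfish community did around the 1990s cod collapse —
no single-species index captures the change. `trawlshift` implements a suite
of complementary community indicators for trawl-survey data, so that
collapse, regime shift and incipient recovery can be tracked along several
axes at once:

* **Robust biomass estimation.** Catch-per-tow data are zero-inflated and
  right-skewed, so average biomass is estimated as

  *E*<sub>zinf-G</sub> = (*m*/*n*) · exp( (1/*m*) Σ<sub>i</sub> ln *b*<sub>i</sub> ),

  the geometric mean of the *m* positive catches scaled by the fraction of
  positive tows among all *n* tows (0 when *m* = 0), with leave-one-tow-out
  jackknife standard errors.
* **Community synchrony.** The Loreau–de Mazancourt variance-ratio statistic
  φ = var(Σ<sub>s</sub> *x*<sub>s</sub>) / (Σ<sub>s</sub> sd *x*<sub>s</sub>)²
  over a running 5-year window, with a one-sided Monte-Carlo randomization
  test (999 replicates; species permuted independently within the window)
  and an increasing/declining classification from the community-total trend.
* **Compositional trajectories.** Bray–Curtis dissimilarity of annual
  relative biomass, displayed by 2-D non-metric multidimensional scaling
  (Kruskal stress-1, SMACOF majorization with isotonic regression,
  multi-start), and a similarity-to-reference-year series rescaled so 100 is
  the reference-year (1981) state and 0 the maximum observed departure.
* **Functional diversity.** Biomass-weighted functional dispersion (FDis) on
  a mixed-trait Gower space (three numeric and three categorical traits,
  PCoA-embedded with Cailliez correction where needed), plus
  community-weighted trait means and categorical biomass shares.
* **Spatial structure.** Voronoi-polygon aggregation of trawls,
  complete-linkage clustering of polygon-period communities into community
  types, and per-year partitioning of the variance in between-polygon
  dissimilarity between depth difference and geographic distance (partial
  adjusted R² from logit/log-transformed regressions).
* **Drivers.** Fishing effort in tonne-days and aggregated z-scored climate
  indices with trailing moving-window smoothing.

A seeded synthetic survey generator (`simulate_survey()`,
`default_collapse_scenario()`) emulates the statistical structure such
analyses assume — depth-structured species niches, four-phase regime
dynamics (stable → synchronous decline → shifted regime → compositional
recovery → biomass growth), zero-inflated lognormal catches, and a 1995
size-dependent gear-catchability shift — and exposes the generating ground
truth, so the whole pipeline is validated end-to-end by parameter recovery.

## Worked example

```r
library(trawlshift)

scenario <- default_collapse_scenario(seed = 1)
report   <- run_pipeline(analysis_config(), scenario)
report
#> pipeline_report (config 5ca0dd24 , seed 1 )
#>   species: 4 commercial + 30 retained total
#>   years: 1981-2013
#>   synchrony windows: 29; NMDS stress: 0.012; clusters: 7

sync <- report$synchrony$all
sync[sync$window_end_year %in% c(1986, 1991, 1993, 2000), ]
#>    window_end_year       phi p_value  direction n_species straddles_gear_change
#> 2             1986 0.5317092   0.320 increasing        30                 FALSE
#> 7             1991 0.9390807   0.001  declining        30                 FALSE
#> 9             1993 0.8573918   0.001  declining        30                 FALSE
#> 16            2000 0.4542455   0.509  declining        30                 FALSE

round(recovery_summary(report), 1)
#>          focal_biomass          total_biomass composition_similarity
#>                    5.6                   11.3                   33.0
#>                   fdis
#>                  133.9
```

Reading the output: synchrony is high and significant (p = 0.001) in the
windows ending 1991 and 1993 — the designed synchronous collapse — and
indistinguishable from the permutation null before the collapse (p = 0.32)
and in the shifted regime (p = 0.51). By the final survey year the scenario
community has regained 11% of its reference-to-trough biomass drop and 33%
of its compositional departure, while functional dispersion is back above
its reference level (134 on the 0–100 anchor scale) — the same ordering of
recovery rates (function > composition > biomass) that motivates tracking
several indicators at once.

`write_pipeline_report(report, "out/")` writes every output family
(biomass, synchrony, NMDS coordinates, FDis, trait means, cluster
assignments and profiles, variance partitions, diversity diagnostics,
recovery series) as tidy CSV tables plus a provenance manifest.

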