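# cpforage

Habitat selection analysis for central-place foraging birds tracked with
GPS loggers.

A provisioning bird at a colony — the classic example is a starling
feeding nestlings on a dairy farm — returns to its nest after every
foraging trip, so the value of a foraging patch depends both on its
land-cover type and on its distance from the nest. `cpforage` implements
the full analysis chain from raw logger files and a land-cover polygon map
to that double answer:

* **QC filtering** of raw fixes: flying birds (speed > 0 m/s), imprecise
  positions (HDOP > 2.5), the 20:00–05:30 night window, non-foraging
  habitat (buildings, gardens, forest, lakes), fixes beyond 999 m, and
  birds with ≤ 50 usable fixes — with per-rule accounting.
* **Availability sampling**: a systematic 50-m grid (4 points/ha) of
  relative availability points (RAPs) over the land-cover map, with
  habitat category and 100-m distance-to-nest bin for every point.
* **Resource selection functions (RSFs)**: use–availability logistic
  regression of fixes (1) against per-bird availability (0) on cover type
  and/or distance bin, with per-bird random effects
  (`bird`, `bird × cover`, `bird × bin`) and a cluster-robust
  fixed-effects fallback. Coefficients are log selection ratios relative
  to *Grazed* and *0–99 m*; `exp(B)` is the selection (odds) ratio.
  Cover-only RSFs on distance zones (0–199, 200–399, 400–999 m) describe
  how selection sharpens with distance.
* **Inference helpers**: selection-ratio strings (`1:2.6`), contrasts
  between categories, continuity-corrected (0.5-count) per-bird selection
  coefficients, t-tests for coefficient differences between models, and
  distance-use summaries with simple normal statistics.
* **Provisioning energetics**: daily travel distance, flight energy,
  nestling energy demand, and the marginal cost of extra foraging
  distance.
* **A synthetic landscape/forager generator** — a Voronoi field mosaic
  plus fixes drawn with known selection and distance decay, contaminated
  with flying/imprecise/night fixes — so the whole pipeline runs and is
  validated without field data.

## Worked example

Simulate a 17-bird colony on a 2-km mosaic, filter, sample availability,
and fit the combined RSF:

```r
library(cpforage)

cfg   <- simulation_config(seed = 1)        # 17 birds x 250 fixes
land  <- generate_landscape(cfg)
fixes <- simulate_fixes(land, cfg)

res  <- apply_qc_filters(fixes, filter_rules(), land)
res$report
#> <filter_report>
#>   input fixes:    4250
#>   excluded speed:     435
#>   excluded hdop:      377
#>   excluded night:     370
#>   excluded habitat:   0
#>   excluded distance:  0
#>   excluded min_fixes: 0
#>   birds dropped:  none
#>   retained:       3068

raps <- generate_raps(land)                  # 50-m grid, 4 points/ha
tab  <- build_use_availability(res$fixes, raps)
fit  <- fit_rsf(tab, "cover_plus_distance")  # mixed model, robust fallback
fit
#> <rsf_fit> cover_plus_distance | method: mixed
#>   use: 3068  availability: 19431  birds: 17
#>     factor       level      B    SE ...
#>      cover  ShortGrass -0.896 0.191
#>      cover  BareGround -1.958 0.192
#>      cover      Meadow -2.344 0.262
#>      cover WinterCrops -4.028 0.385
#>   distance   100-199 m -0.651 0.114
#>   ...
```

The generator's true cover coefficients were −0.94, −1.83, −2.55 and
−3.87: the fit recovers them within its standard errors. Coefficients
convert to the conventional ratio strings — how many times *less* each
category is used than Grazed at equal availability:

```r
odds_ratio(-0.896)$display   # "1:2.4"
odds_ratio(-4.028)$display   # "1:56"
```

And the provisioning energetics: an extra 100 m of one-way foraging
distance at 250 roundtrips/day, 10 m/s and 9.4 W costs 47 kJ/day, about
29% of one nestling's 160 kJ daily demand:

```r
marginal_cost_share(100)
#> [1] 0.29375
```

`run_pipeline(run_config(...))` chains every stage into a reproducible run
directory (filter report, RAP table, model CSVs, difference tests, ratio
report, figures, log), and `inst/cli/cpforage.R` is a thin command-line
wrapper (`simulate | filter | raps | rsf | report | energetics | run`).

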