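---
title: "Methods: central-place resource selection from GPS telemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: central-place resource selection from GPS telemetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpforage)
```

## The problem

A provisioning songbird at a colony is a central-place forager: every
foraging trip starts and ends at the nest, so the cost of using a patch
grows with its distance from the colony. Given GPS-logger fixes from tagged
birds and a polygon map of land-cover categories around the colony,
`cpforage` estimates *which* cover types the birds select, *how strongly*
use decays with distance to the nest, and how the two interact — together
with the quality-control filtering, availability sampling, and downstream
summaries that such an analysis needs. A synthetic landscape-and-forager
generator with known selection structure makes every stage testable without
field data.

## The model

Habitat selection is modelled with a use–availability resource selection
function (RSF). Observed fix locations are "use" (response 1); a systematic
sample of points describes "availability" (response 0). A logistic
regression of the response on habitat category and 100-m distance-to-nest
bin estimates, for each level, the log of the ratio by which that level is
used relative to a reference level at equal availability:

$$\operatorname{logit} P(\text{use}) = \alpha + B_{c} + D_{b},$$

with treatment coding against the references *Grazed* (cover) and *0–99 m*
(distance). The intercept is uninformative — it only reflects the arbitrary
ratio of fixes to availability points — but each coefficient $B$ is a log
selection ratio and $e^{B}$ the selection (odds) ratio familiar from the
RSF literature. Three model forms are supported: cover only, distance only,
and cover plus distance as main effects; separate cover-only fits on
distance-zone subsets (0–199, 200–399, 400–999 m) stand in for the
cover-by-distance interaction, which is rarely estimable in unbalanced
telemetry data.

### Random effects and the estimation methods

Birds differ both in their fix/availability ratio and in their individual
selection. `fit_rsf()` offers three estimators:

* `"mixed"`: a binomial GLMM with independent Gaussian random intercepts
  for bird, bird × cover level, and bird × distance-bin level. This is the
  portable reading of a model with a subject random factor plus
  subject-by-habitat interaction random terms; the exact covariance
  semantics of any particular proprietary implementation are not
  reproduced. `lme4::glmer` is used with `nAGQ = 0` on the
  count-aggregated table (the aggregation is likelihood-identical and
  orders of magnitude faster). Denominator degrees of freedom are the
  residual-df approximation; no Satterthwaite approximation exists for
  GLMMs in `lme4`, and df values are deliberately not a quantity this
  package tries to match to any other software.
* `"fixed_robust"`: fixed-effects logistic regression with cluster-robust
  standard errors by bird, CR3 (jackknife-type) small-sample correction,
  and t statistics on (birds − 1) df. This is the mandatory fallback when
  the mixed model fails to converge — unbalanced telemetry data make that
  a routine event — and the recommended estimator for large simulation
  studies, where tens of thousands of fits are needed. With ~17 clusters
  the plain CR1 estimator is anti-conservative; CR3 is the standard
  few-cluster choice. When CR3's leverage adjustment is singular (a
  cluster that fits itself exactly) the implementation degrades to CR2
  then CR1; with a single bird there is nothing to cluster on and
  model-based covariance is used.
* `"fixed"`: plain maximum-likelihood logistic regression with model-based
  covariance, appropriate when observations are genuinely independent —
  e.g. sharp-null simulations without per-bird heterogeneity, where it is
  exactly calibrated.

`"auto"` (the default) tries `"mixed"` and falls back to
`"fixed_robust"`, flagging the fallback in the fit object.

Coefficients with $|B| > 15$ or $SE > 50$ are flagged non-estimable
(complete or quasi-complete separation, e.g. a category never used) rather
than reported as huge numbers, and joint tests involving them are skipped.
The overall (type-III style) effect test is a Wald F on the factor's
coefficients using the fitted covariance; the inverse is computed through
an eigendecomposition that drops null directions, because a cluster-robust
covariance of $q$ coefficients has rank at most the number of clusters.

## Filtering raw fixes

The QC rules retain only precise, stationary, daytime, foraging-relevant
fixes. Defaults: exclude fixes with speed > 0.0 m/s (flying) or
HDOP > 2.5 (imprecise, roughly worse than 10 m); exclude the night window
[20:00, 05:30) (roost movements) — 20:00 itself is excluded, 05:30
retained; exclude non-foraging cover (buildings, gardens, forest, lakes);
exclude fixes at ≥ 999 m from the colony centre; and finally drop whole
birds with ≤ 50 surviving fixes. Speed and HDOP thresholds are
*inclusive-keep*: equality survives, because the exclusion rules are
written as strict inequalities. Rules are applied in the order listed and
each excluded fix is attributed to the first rule that rejects it; since
every rule is a pure per-fix predicate, the retained set is independent of
the order — only the per-rule accounting depends on it. A fix lying
outside every polygon cannot be a foraging observation and is counted
under the distance rule rather than raising an error. Timestamps are taken
as already-local; no daylight-saving arithmetic is attempted (tracking
weeks sit inside one DST regime). An optional parse-time switch drops the
first calendar day of each logger (a start-up exclusion for handling
effects); it is off by default because synthetic data have no such
artefact.

## Availability sampling

Availability is measured by relative availability points (RAPs): the
intersections of a square grid, 50-m spacing by default (4 points per
hectare), anchored at the colony centre — the anchoring is a choice; it
makes the sample translation-invariant and reproducible, since the true
grid origin of any field study is unknowable. Points are kept when they
fall strictly within 999 m of the colony and in a foraging category,
mirroring the exclusion of non-foraging cover from use. Distances use the
colony centre as the common central place for all nests. Distance bins are
half-open 100-m annuli, bin = ⌊d/100⌋.

## The synthetic generator

`simulation_config()` + `generate_landscape()` + `simulate_fixes()`
emulate a mid-size colony study:

* **Landscape**: a Voronoi tessellation of uniformly placed seeds over a
  2-km square, cells labelled greedily so realised areal proportions
  inside the 1-km classification disc match the requested mix. Cells with
  a typical diameter of 200 m give a convex, field-like parcel mosaic.
  The default mix has five foraging categories (89.6% of area) and 10.4%
  excluded cover, the share of non-foraging area typical of such a farm
  landscape.
* **Fixes**: locations are drawn from a 10-m lattice over the disc —
  finer than the 50-m availability grid, so availability sampling is
  honestly decoupled from generation — with weight
  $\exp(B_c + D_b)$, the generative counterpart of the fitted RSF. The
  default coefficients are the selection strengths and distance decay of
  a strongly central-place-bound starling colony (Grazed reference;
  Short Grass −0.94, Bare Ground −1.83, Meadow −2.55, Winter Crops
  −3.87; decay from 0 at 0–99 m to about −5 beyond 700 m). Defaults use
  17 birds × 250 fixes.
* **Heterogeneity**: optional zero-mean Gaussian deviations (SD 0.5 by
  default) are added to each bird's category log-strengths, echoing
  variance components in the 0.3–2.6 range seen in colony data, so the
  random-effect machinery has real work to do.
* **Contamination**: configured fractions of fixes (10% each by default)
  are flagged flying (speed uniform on 1–15 m/s; clean fixes have speed
  exactly 0), imprecise (HDOP uniform on 2.6–6; clean HDOP below 2.5), or
  night (re-timed into 20:00–05:30). Daylight fixes run at 1-minute
  cadence from 05:30.

The generator is deliberately *not* a behavioural movement model: there
are no trajectories, trips, or autocorrelated steps, and no battery or
duty-cycle effects beyond the fixed cadence. Consequences: passing tests
demonstrate that the estimation pipeline recovers a known selection
structure from multinomially sampled points, not that it is robust to
serial autocorrelation of real tracks (in the model, that burden falls on
the per-bird random effects) or to trip-structured spatial clustering.

## Calibration experiments and their design

Two simulation suites check the estimator itself (they run in the test
suite; sizes were chosen to give tight binomial Monte-Carlo error at
manageable cost):

* **Parameter recovery** — 100 replicates of 17 birds × 250 fixes with
  the default (Table-style) selection and decay and per-bird SD 0.5; the
  combined RSF must cover each true cover coefficient in at least 90 of
  100 replicate CIs. Fitted with `fixed_robust` (CR3, t on 16 df).
* **Type-I error** — 500 replicates with all selection coefficients zero,
  no decay and no heterogeneity; the overall cover-effect F-test must
  reject at the 5% level between 3% and 8% of the time. Fitted with
  `"fixed"`, the exactly-calibrated estimator for independent data.

Both suites draw availability as a *random* sample of the generation
lattice, independently for each bird, rather than replicating the one
systematic 50-m grid per bird. The reasons are statistical, not
cosmetic. First, a systematic grid's availability measurement error is a
fixed quantity for a given landscape: across replicates it acts as a
constant offset that no model standard error represents, so CI coverage
and test size would be distorted by a nuisance unrelated to the estimator
under test. Second, replicating one availability sample per bird
fabricates precision: seventeen copies of the same 1,250 points enter the
likelihood as 21,250 independent observations. In a pilot of this design
the null rejection rate was 0.64 instead of 0.05. With per-bird random
availability the case–control logistic model is correctly specified and
both suites are clean. The systematic-grid operation itself is validated
separately against brute-force lattice enumeration and analytic areal
proportions, which is the appropriate oracle for a deterministic
sampling scheme.

A related caveat worth stating: with between-bird heterogeneity, the
pooled fixed-effects estimator targets a population-averaged coefficient
that is slightly attenuated relative to the subject-specific generative
value (about +0.1 on a coefficient of −3.9 at SD 0.5); the mixed model
removes most of this at the price of heavier computation and optimistic
Wald intervals at 17 clusters. The CR3 intervals are wide enough to cover
the generative values despite the attenuation, which is why they are the
default for the recovery suite.

## Derived quantities

* `odds_ratio()` converts a coefficient to the conventional ratio string:
  `1:x` for negative coefficients, `x:1` for positive, one decimal below
  10 and integers from 10 up (the convention behind strings like `1:2.6`
  and `1:48`).
* `coefficient_contrast()` compares two levels sharing a reference:
  difference of coefficients, anti-logged, with a normal 95% CI from the
  summed squared SEs. The independence assumption is stated explicitly:
  when both coefficients come from the same fit their positive covariance
  would narrow the interval, so the plug-in CI is conservative on the
  upper side.
* `continuity_sc()` is the count-based per-bird selection coefficient
  `ln((U_f/U_tot)/(A_f/A_tot)) − ln((U_r/U_tot)/(A_r/A_tot))` with the
  0.5-count substitution applied to any zero count (use *or*
  availability), keeping the estimate finite — e.g. 0 of 24 fixes becomes
  0.5/24 ≈ 0.021. With large counts it converges to the closed-form 2×2
  log odds ratio.
* `coef_difference_test()` compares the same level across two fits:
  `t = (B₁ − B₂)/√(SE₁² + SE₂²)` on df₁ + df₂ degrees of freedom. The
  subtraction order is recorded explicitly in the output
  (first-minus-second by default) since the sign convention is otherwise
  ambiguous. Summed df is a pragmatic convention, not an exact
  distributional result.
* `mean_sc()` and `distance_use_summary()` use simple normal statistics
  (mean, sd/√n, ±1.96·SE) on per-bird values; arithmetic rather than
  logit-back-transformed means are used, accepting a slight conservative
  bias, and display CIs are truncated to [0, 1] without altering the
  stored values.
* The energetics module is plain arithmetic on a provisioning budget:
  `daily km = roundtrips × 2 × one-way/1000`;
  `kJ = (m / speed) × power / 1000`; nestling demand = food mass × energy
  density, with the prey-count equivalent; and the marginal cost of extra
  distance as a fraction of one nestling's demand. With the default
  parameters (250 roundtrips/day, 10 m/s, 9.4 W, 40 g/day, 0.25 g and
  4 kJ/g prey) an extra 100 m one-way costs 47 kJ/day ≈ 29.4% of one
  nestling's 160 kJ daily demand. Raw fractions are returned; rounding is
  left to presentation.

## Numerical and degenerate-input choices

* Polygon operations are exact planar geometry on metre coordinates:
  Voronoi cells by iterated half-plane clipping, disc clipping against an
  inscribed 256-gon, shoelace areas, and a crossing-number point-in-polygon
  test that counts boundary points as inside so the documented tie-break
  (lowest polygon id wins) is deterministic. Points in no polygon yield an
  `NA` category sentinel, never an error.
* Distances ≥ 1000 m have no bin (`NA`); callers drop them.
* All generator randomness derives from the config seed via isolated RNG
  scopes, so identical seeds give byte-identical outputs and library-level
  RNG state is never disturbed.
* Zone fits drop birds with ≤ 20 fixes in the zone (strict >) and
  categories with zero use in the zone, reporting both; a zone left with
  fewer than two categories is skipped with a report entry rather than
  fitted.

## Known limitations

* No step-selection or conditional-logistic designs; no spatial
  autocorrelation model; no Bayesian fitting.
* Denominator df are approximations; df-sensitive comparisons across
  software will differ.
* The availability grid's discretisation error is real and systematic for
  any single landscape (see the calibration discussion above); at 50-m
  spacing it is small relative to coefficient SEs in realistic designs,
  but it does not vanish with more fixes.
* Geographic coordinates must be planar metres; re-projection is a
  documented pre-step outside the package.
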