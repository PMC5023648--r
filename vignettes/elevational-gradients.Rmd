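---
title: "Methods: banding, area correction and spatial models for elevational diversity gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: banding, area correction and spatial models for elevational diversity gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(altiband)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, and the design
choices made where the underlying methodology is genuinely open. Nothing
quantitative is claimed here that the test suite or `scripts/acceptance.R`
does not itself compute.

## The analysis in one paragraph

A mountain checklist records, for each species, the minimum and maximum
elevations at which it has been found, plus its life form and taxonomy.
Treating each species as continuously present between its recorded limits
(*interpolation*), richness can be counted in altitudinal bands. But band
area varies enormously along a gradient, and richness scales with area, so
an apparent mid-elevation richness peak may be nothing but hypsography.
The package removes the area effect in two independent ways — rescaling by
a fitted power-law species–area relationship (method 1) and re-counting in
equal-area bands (method 2) — then asks which correction better preserves
the signal of the abiotic predictors (elevation, mean annual temperature
MAT, mean annual precipitation MAP, and the mid-domain-effect prediction),
using spatially explicit regressions. Bands along one gradient are not
independent observations: residuals are autocorrelated, which is measured
with Moran's I correlograms and absorbed with simultaneous autoregressive
(SAR) error models.

## Band construction

`make_equal_elevation_bands(domain_min, domain_max, width)` tiles the
domain with fixed-width intervals. Intervals are half-open
`[lower, upper)` with the top band closed — the one convention under which
every elevation belongs to exactly one band. The span must divide evenly
by the width; a silent partial band would distort the top band's area, so
it is an error instead. The study-scale default is a 1350–5050 m domain in
100 m bands, giving 37 bands.

Band area is planimetric: cell area (default 900 m², a 30 m DEM cell)
times the number of cells in the band. Cells outside the domain are
excluded and counted, never silently dropped.

`make_equal_area_bands(grid, n_bands, seed)` implements the jitter-and-rank
construction: integer DEM elevations get an independent U(−0.5, +0.5)
perturbation (one uniform per cell in raster row-major order), the
jittered values are sorted, and cells are cut into `n_bands` contiguous
rank groups whose sizes differ by at most one (any remainder cells go to
the lowest-index bands — the split rule is otherwise underdetermined).
Band boundaries are midpoints between the two jittered values straddling
each cut, clamped to the domain at the ends. The midpoint rule makes the
boundary independent of the side from which it is approached; how GIS
class-boundary tools place these limits internally is not documented, so
this choice is stamped into the output manifest. Widths then vary
inversely with hypsographic density: the narrowest band sits near the
hypsographic mode and the widest at the sparse top of the gradient.

## Richness counting

A species' closed range `[elev_min, elev_max]` is counted into every band
whose interval it intersects. One boundary case matters: a range ending
exactly at a band's *lower* bound is counted into that band (conservative
presence under the continuous-distribution assumption); a range meeting
only a band's upper bound is not, because that point belongs to the next
band under the half-open convention. Presence sets are always contiguous
runs of band indices.

Nine variables are counted per band: species, genus and family richness
(genus/family presence is derived from species presence, not from
independent range data); tree, shrub and herb species richness; and
species richness in three elevational range-size groups — Group I
(< 150 m), Group II (150–500 m, both endpoints inclusive; the verbal
definition "between 150 and 500" is ambiguous, and the inclusive reading
is recorded in the manifest), Group III (> 500 m). Two partition
identities hold by construction and are enforced in tests: the life-form
and the group richness sum to species richness in every band, and
`S ≥ G ≥ F`.

Method 2 is deliberately *not* a separate code path: the identical
counting operation run on the equal-area scheme yields the corrected
richness, so any counting bug would hit both gradients equally.

Species whose presence set has cardinality 1 form the "single-band"
subset; counting them needs no interpolation, which makes the subset a
useful check that interpolation is not manufacturing the mid-elevation
peak. Note the subset is a superset of the zero-range (single-record)
species: a species with a small nonzero range can also fit inside one
band.

## Species–area relationship and method 1

Three versions are fitted by OLS on the same positive-richness,
positive-area band subset: untransformed (`S ~ A`), semi-log
(`S ~ log A`) and log–log (`log S ~ log A`); the log–log version is the
power law `S = c·A^z` with slope `z`. Version selection uses the
small-sample Akaike criterion

`AICc = −2 logLik + 2K·n/(n − K − 1)`,

with the Gaussian log-likelihood at the ML residual variance and `K = 3`
(slope, intercept, error variance — the standard count for simple linear
regression; any other constant `K` shifts all three AICc values equally
and cannot change the selection). A rival within 2 AICc units is flagged
co-best. Two conventions to be aware of: logarithms are natural (the
exponent `z` is base-invariant; the intercept is reported in natural-log
units), and the AICc comparison pits likelihoods on each version's own
response scale (`S` versus `log S`) without a Jacobian correction — the
convention of the applied species–area literature this package mirrors,
kept deliberately so that selections are comparable with published
analyses. With fewer than five usable bands the AICc penalty is undefined
and the fit carries `aicc = NA`; such fits cannot enter selection.

Method 1 rescales `TRcor1 = 100·TRobs / A^z`. When richness follows the
power law exactly, the correction is algebraically constant at `100·c`,
and refitting the corrected values on log-area gives an exactly zero slope
whenever `z` came from the same data — both are enforced as tests. Because
the scale of `TRcor1` depends on the area unit through `c`, the unit
(km²) is stamped into the output.

## Mid-domain effect null model

The null model preserves the empirical multiset of range sizes and
randomizes placement: a species with range size `r` in a domain of span
`D` has its midpoint drawn uniformly on the feasible interval
`[domain_min + r/2, domain_max − r/2]`, so no range crosses a hard
boundary. This is the uniform-midpoint variant — the canonical
range-size-preserving null; which exact algorithm the classic
range-placement software uses in any given study is rarely reported, so
the variant is recorded in the manifest. Per-band presence uses the same
interval-intersection rule as the richness counter; the per-band mean over
`n_sim` simulations (default 1000) is the MDE prediction, with 2.5 % and
97.5 % simulation quantiles retained.

The uniform-midpoint model admits a closed form: a species hits band
`[a, b]` exactly when its midpoint lies in `[a − r/2, b + r/2]`, so the
presence probability is the length of that interval clipped to the
feasible one, divided by `D − r` (and 1 when `r = D`). Expected band
richness is the sum over species. `analytic_mde_expectation()` implements
this and serves as the simulator's independent oracle.

On calibration testing: a "simulation within 3·SE of the expectation in
every band" assertion repeated over many bands and cases is a large family
of simultaneous comparisons, and a correctly calibrated simulator *will*
produce occasional ~3.5·SE excursions. The tests therefore assert
agreement at a controlled familywise level (a Šidák-corrected bound plus
the nominal 3·SE exceedance rate and a zero-bias check on the mean
z-score), which is the statistically sound reading of the per-band rule.

## Spatial statistics

Bands are 37 observations along a single geographic axis. Moran's I at a
distance class uses raw binary weights connecting pairs whose separation
falls in `(d − step/2, d + step/2]`:

`I = (n/S) · ΣΣ w_ij (x_i − x̄)(x_j − x̄) / Σ (x_i − x̄)²`,

with `S` the number of links. On 100-m equal-elevation bands the classes
are exactly 100 m, 200 m, … . Correlograms attach a two-sided permutation
p-value per class (999 permutations by default, fixed seed, extremeness
measured around the null expectation `−1/(n − 1)`).

Polynomial models of each richness variable on each predictor are fitted
at orders 1 and 2; coefficients are reported in the Q/S/C convention
(quadratic, slope, constant). Order selection again uses AICc with the
parsimony rule: the higher order must win by at least 2 units, otherwise
the first-order fit is kept.

The SAR error model is `y = Xβ + u`, `u = λWu + ε` with `W`
row-standardized. For fixed `λ` the model is a GLS whose whitened form
`(I − λW)y ~ (I − λW)X` is solved by least squares; the profile
log-likelihood adds the Jacobian `Σ log(1 − λe_i)` over the eigenvalues of
`W` (n = 37 makes the eigendecomposition trivial), and `λ` is profiled out
by one-dimensional optimization on (−1, 1). At `λ = 0` the fit reduces
exactly to OLS, and the SAR likelihood can never fall below the OLS
likelihood (nesting) — both are tested. Pseudo-R² is the squared Pearson
correlation between the observations and the full prediction
`Xβ + λW(y − Xβ)` (trend plus spatial signal); the trend-only value is
reported alongside for transparency. Model significance is a likelihood
ratio test against the intercept-only SAR on the same weights;
coefficient p-values are asymptotic z-tests; significance thresholds in
printed tables are the conventional 0.05/0.01/0.001. No multiple-testing
correction is applied across the battery, matching standard practice in
this literature.

Two weight-scheme decisions are recorded in the manifest. First,
equal-elevation analyses use 100-m distance-class weights on band
mid-elevations, while equal-area analyses default to rank adjacency
(band *i* neighbors *i* ± 1): equal-area mids are irregular, and a fixed
100-m radius would isolate the wide bands entirely. Second, bands with
zero richness for a given group are dropped from that group's models
(their log-richness is undefined and their zero says only that the group
is absent), and the weights are *recomputed on the analyzed subset* —
whether published analyses rebuilt their neighbor lists on such subsets is
typically unstated, so the choice is made explicit here.

The method comparison collects the selected SAR fit per richness group ×
predictor for `TRcor1` and `TRcor2` and flags the method with the larger
pseudo-R²; ties are flagged as such. Whether method 1 or method 2 wins is
a property of the data, not of the package — on synthetic mountains the
outcome varies with the generator seed, and the pipeline reports the win
counts rather than asserting a winner.

## The synthetic mountain: what it emulates, and what it does not

The generator reproduces the *statistical structure* the analysis needs,
not terrain. Cell elevations are placed at stratified quantiles
(midpoint probabilities `(i − 0.5)/n`) of a split-normal hypsographic
density truncated to the domain, then spatially permuted by seed. The
split normal is the simplest unimodal skew family whose mode is a direct
parameter; stratification makes the realized band-area histogram match the
target density for any grid size, where an i.i.d. draw of moderate size
can shift the mode band by sampling noise. Elevations are rounded to
integer metres because the equal-area jitter rule presupposes an integer
DEM. Defaults: domain 1350–5050 m, area mode at 2700 m (the band-area
hump), spreads 450 m below / 750 m above the mode (the domain extends
further above the mode than below), a 100 × 100 grid of 900 m² cells.

MAT is a linear lapse from 16 °C at the base at 0.006 °C/m; MAP follows a
piecewise-linear rise–fall–rise profile (up to 1200 mm at 1900 m, down to
912 mm at 4200 m, rising again to the top). Optional zero-mean Gaussian
cell noise is available for both; the band-scale noise structure of
interpolated climate surfaces is not documented by their providers, so
the default is 0 and the knob is exposed.

The checklist defaults emulate a rich subtropical montane flora: 2028
species, ~66 % herbaceous, nested genus/family labels with mean sizes
3.2 species/genus and 4.6 genera/family, range-size groups in proportions
830:554:644 (uniform range sizes within `[0, 150)`, `[150, 500]`,
`(500, span]`), and ~35 % single-record species (range size zero, a subset
of Group I). Range midpoints follow a unimodal Gaussian-bump profile
peaking at 40 % of the domain span with spread a quarter of the span —
montane richness concentrates at mid elevations, and a unimodal true
profile is what makes the hump-shaped-pattern checks meaningful; a
uniform-midpoint option is retained. All sampling is seeded and runs
through an RNG-state-preserving wrapper, so identical parameters and seed
give byte-identical output and no global state leaks.

What passing tests on this generator do **not** show about real data: no
spatial occurrence structure below the band level (the analysis is purely
banded), no detection error or survey-effort gradients, no taxonomic
autocorrelation of ranges (congeners are placed independently), no
slope-corrected surface areas, and climate that is an exact function of
elevation unless noise is requested. Conclusions about which correction
method "wins" on a real mountain require the real checklist and DEM.

## Numerical choices and degenerate inputs

* Optimization of the SAR `λ` uses Brent's method on the admissible
  interval intersected with (−0.999, 0.999), tolerance 1e−9; its standard
  error comes from the numerically differentiated profile likelihood.
* `aicc()` refuses `n ≤ K + 1` (the penalty is undefined or negative
  infinity); fits at exactly the minimum usable size report `NA` instead.
* Moran's I refuses constant inputs (zero denominator) and classes with no
  pairs; correlogram classes without pairs are omitted with a warning.
* Equal-area banding refuses `n_bands` larger than the cell count; a
  single-cell grid is a valid degenerate DEM.
* Empty checklists yield all-zero richness tables, not errors; duplicate
  species ids with conflicting ranges are an error (no silent merging).
* Zero-range species are placed as points and occupy exactly one band.

## Problem sizes

The default pipeline (10 000 cells, 2028 species, 37 bands, 1000 MDE
simulations, 432 regression fits, residual correlograms for the species
richness models) runs in a few seconds. The test suite uses scaled-down
versions of the same conditions — e.g. 40 × 40 grids and 400-species
checklists for end-to-end runs, 60–200 replicates for parameter-recovery
simulations, 999 permutations only where a single test needs them — sizes
chosen so each property is measured with comfortable statistical margin.
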