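# altiband

Altitudinal banding, area correction and spatial analysis of elevational
diversity gradients.

## The problem

Taxon richness along mountain gradients is usually hump-shaped, peaking at
mid elevations — but the *land area* available in each elevational band is
itself hump-shaped, and the species–area relationship means band area alone
can manufacture (or mask) a richness peak. Before asking whether
temperature, precipitation or geometric constraints (the mid-domain effect)
drive an elevational diversity pattern, the area effect has to be removed.
Two corrections are in use:

* **Method 1** — fit the power-law species–area relationship
  `S = c·A^z` across bands (log–log OLS, version chosen by small-sample
  AICc) and rescale observed richness to `TRcor1 = 100·TRobs / A^z`;
* **Method 2** — rebuild the gradient as *equal-area* bands (jitter the
  integer DEM elevations by U(−0.5, +0.5), rank-split the cells into bands
  of equal cell count) and simply re-count richness.

`altiband` implements both corrections plus everything around them for a
banded checklist analysis: interpolated richness counting for nine taxon
groups (species/genus/family, tree/shrub/herb, and narrow/intermediate/wide
range-size groups), a uniform-midpoint mid-domain-effect null model with a
closed-form expectation, Moran's I correlograms (Eq. form
`I = (n/S)·ΣΣ w_ij (x_i−x̄)(x_j−x̄) / Σ(x_i−x̄)²` on binary distance-class
weights with permutation tests), simultaneous autoregressive (SAR) error
models `y = Xβ + u, u = λWu + ε` fitted by profile maximum likelihood, and
the method comparison by SAR pseudo-R² (squared Pearson correlation of
observed values with the trend-plus-signal prediction). A synthetic
mountain generator — hump-shaped hypsography, linear temperature lapse,
rise–fall–rise precipitation profile, and a nested-taxonomy checklist with
a realistic range-size mixture — makes the whole pipeline testable without
external data.

Intended users: macroecologists analysing elevational checklist data, and
anyone needing a reproducible, scripted equivalent of the usual
GIS + spreadsheet + spatial-regression band workflow.

## Worked example

```r
library(altiband)

cfg <- run_config(seed = 1)     # default synthetic study conditions
run <- run_pipeline(cfg)
print(run)
```

```
<altiband_run>
  DEM: 10000 cells, domain [1350, 5050] m; checklist: 2028 species
  bands: 37 equal-elevation (100 m), 37 equal-area
  species richness peaks (m): obs 3000, cor1 4600, cor2 2976.08
  SAR pseudo-R2 comparison: method1 wins 14, method2 wins 22, ties 0
```

Observed species richness peaks at 3000 m — an interior (hump-shaped)
maximum, as does the method-2 corrected richness (2976 m), while the
method-1 correction relocates the maximum towards the sparse top of the
gradient. Across the 9 richness groups × 4 predictors, the equal-area
recount preserves more of the abiotic signal (larger SAR pseudo-R²) in 22
of 36 cells on this synthetic mountain.

The species–area fit behind method 1:

```r
print(run$species_area$S$best)
```

```
<species_area_fit> loglog: z (power-law exponent) = 0.3800, intercept = 6.7938
  adj R2 = 0.9269, p = 1.12e-21, AICc = -29.18 (dAICc = 0.00), n = 37 (0 dropped)
```

The log–log (power-law) version wins the AICc race decisively (its rivals
sit hundreds of AICc units higher), with `z ≈ 0.38` — inside the range
typically reported for nested species–area exponents.

Every stage is also callable on its own — `make_equal_elevation_bands()`,
`make_equal_area_bands()`, `richness_table()`, `fit_species_area()`,
`correct_method1()`, `simulate_mde()`, `morans_i()`, `correlogram()`,
`fit_polynomial()`, `fit_sar_error()`, `compare_methods()` — on data read
with `read_esri_ascii()` / `read_checklist_csv()`, and
`run_pipeline(cfg, out_dir = "out")` writes every table as CSV plus a JSON
manifest of seeds and conventions.

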