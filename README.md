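# mesoflux

Leaf photosynthesis, mesophyll conductance and airspace diffusion traits in R.

Photosynthetic capacity in broadleaf trees is set jointly by biochemistry
(Rubisco carboxylation, RuBP regeneration, triose-phosphate use) and by how
easily CO2 diffuses from the stomata through the intercellular airspace (IAS)
to the chloroplasts. Screening germplasm — walnut accessions being the
motivating case — therefore needs three measurement chains analysed
consistently: CO2 response curves from a gas-exchange cuvette, chlorophyll
fluorescence, and 3D microCT scans of the mesophyll. mesoflux implements all
three, plus seeded synthetic-data generators with known ground truth so every
estimator can be validated end to end, and the study-level statistics used to
relate traits to climate-of-origin and dehydration response.

## What it computes

**FvCB curve fitting.** Net assimilation is the minimum of the three
limitation states at the chloroplast CO2 mole fraction $C_c$:

$$A_n = \min\!\left(
\frac{V_{cmax}(C_c-\Gamma^*)}{C_c+K_c(1+O/K_o)},\;
\frac{J(C_c-\Gamma^*)}{4C_c+8\Gamma^*},\;
3\,\mathrm{TPU}\right) - R_d,
\qquad C_c = C_i - A_n/g_m .$$

`fit_aci()` estimates $V_{cmax}$, $J_{max}$, TPU and $g_m$ from an
$A_n$–$C_i$ curve by exhaustive search over ordered limitation partitions,
closed-form (quadratic) operating-point solutions per branch, trust-region
least squares and seeded multistart. `amax()` returns the CO2-saturated rate
$3\,\mathrm{TPU}-R_d$; `an_at_reference_ca()` interpolates $A_n$ at a
reference ambient partial pressure (40.4 Pa by default); `leak_correct()`
applies an empty-chamber cuvette leak calibration.

**Variable-J mesophyll conductance.** `electron_transport()`
($J_{flu}=\Phi_{PSII}\cdot \mathrm{PPFD}\cdot\alpha\cdot\beta$),
`gm_variable_j()` (Harley's estimator), `chloroplast_co2()`
($C_c = C_i - A_n/g_m$) and `laisk_estimate()` (the common intersection of
low-CO2 response lines at several irradiances, yielding $C_i^*$ and $R_d$).
Defaults are walnut-calibrated: $\alpha=0.853$, $\beta=0.5$, $R_d=0.73$,
$\Gamma^*=C_i^*=38.18$.

**MicroCT diffusion anatomy.** From a segmented label volume:
porosity $\theta_{IAS}$, IAS:cell ratio, exposed mesophyll surface density
$SA_{mes}/V_{mes}$, vein fraction, leaf/mesophyll thickness, stomatal
density, geodesic tortuosity $\tau_{leaf}=\overline{(L_{geo}/L_{Euc})^2}$,
lateral path lengthening $\lambda_{leaf}=\overline{L_{Euc}/L_{epi}}$ (both
averaged at the edge of mesophyll cells; distance fields via multi-source
Dijkstra through the airspace and exact Euclidean transforms, implemented in
C++), and the hypostomatous airspace conductance

$$g_{IAS} = \frac{\theta_{IAS} D_m}{0.5\,L_{mes}\,\tau_{leaf}\,\lambda_{leaf}}$$

converted to mol m⁻² s⁻¹ bar⁻¹.

**Synthetic data.** `make_leaf_phantom()` (labeled leaf volumes with exact
by-construction truth), `simulate_gas_exchange()` (curves generated jointly
with the stomatal supply relation and invertible fluorescence records),
`apply_dehydration()` (thinner leaf, higher porosity by construction),
`make_climate_table()` (sinusoidal monthly climate with analytic seasonality
CV).

**Study statistics.** `wue_i()`, `seasonality_cv()`, `percent_change()`,
`bonferroni_alpha()`, `correlation_matrix()`, `gias_contribution()`
($100\,g_m/g_{IAS}$), `dehydration_comparison()`, and a `run_all()` pipeline
with input validation and provenance.

## Worked example

```r
library(mesoflux)

truth <- fvcb_params(Vcmax = 100, Jmax = 150, TPU = 9.08, Rd = 0.73, gm = 0.2)
curve <- simulate_gas_exchange(sim_spec(truth, gs = 0.3, noise_sd = 0.3, seed = 42))
fit <- fit_aci(curve, seed = 1)
fit
#> FvCB A-Ci fit
#>   Vcmax = 109.834  Jmax = 152.561  TPU = 9.219 (umol m-2 s-1)
#>   gm = 0.1761 mol m-2 s-1   Rd = 0.730   Gammastar = 38.18
#>   SSE = 0.3917 over 12 points; blocks at 7/8
round(amax(fit), 2)
#> [1] 26.93
```

The fitted $A_{max}$ of 26.93 umol m⁻² s⁻¹ recovers the generating plateau
($3 \times 9.08 - 0.73 = 26.51$) to 1.6% despite the added noise; TPU and
$J_{max}$ are tight, while $V_{cmax}$ and $g_m$ show the expected
single-curve ridge (see the methods vignette). The fluorescence route gives
an independent $g_m$ from the same simulated records, here using the
ambient-CO2 points where the variable-J estimator is well conditioned:

```r
ok <- !is.na(curve$PhiPSII) & curve$An > 5 & curve$Ca <= 600
gm_flu <- gm_variable_j(curve$An[ok], curve$Ci[ok],
                        electron_transport(curve$PhiPSII[ok], curve$PPFD[ok]))
round(median(gm_flu), 4)
#> [1] 0.2148
```

A synthetic leaf volume runs through the full anatomy chain:

```r
ph <- make_leaf_phantom(leaf_phantom_spec(dims = c(48, 26, 26), seed = 7))
round(mesophyll_traits(ph$volume), 4)
#>   theta_IAS ias_to_cell sa_density tau_leaf lambda_leaf L_leaf L_mes
#> 1       0.3      0.4464     0.4008   1.9784      1.1569   31.2    26
#>   vein_fraction  g_IAS
#> 1        0.0232 6.3466
```

Porosity hits its 0.30 target exactly (the generator closes that loop by
construction); tortuosity near 2 reflects the few, point-like stomata of
this small phantom. The closed-form conductance for field-typical values:

```r
g <- gias(0.3, L_mes = 200, tau_leaf = 1.5, lambda_leaf = 1.2)
round(as.numeric(g), 3)   # mol m-2 s-1 bar-1
#> [1] 1.049
```

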