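---
title: "Methods: leaf photosynthesis, mesophyll conductance and airspace diffusion traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leaf photosynthesis, mesophyll conductance and airspace diffusion traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoflux)
```

mesoflux implements the computational chain used to characterise
photosynthetic capacity and CO2 diffusion in broadleaf tree leaves, with a
calibration oriented at walnut (*Juglans*-type) material: biochemical
capacity from CO2 response curves, mesophyll conductance from chlorophyll
fluorescence, and gas-phase diffusion anatomy from segmented microCT volumes.
This vignette records the models, the numerical decisions, and the limits of
what the synthetic validation can show.

## The FvCB model and the operating point

Net assimilation is the minimum of three limitation states evaluated at the
chloroplast CO2 mole fraction $C_c$:

$$A_c = \frac{V_{cmax}\,(C_c - \Gamma^*)}{C_c + K_c\,(1 + O/K_o)} - R_d,
\qquad
A_j = \frac{J\,(C_c - \Gamma^*)}{4C_c + 8\Gamma^*} - R_d,
\qquad
A_p = 3\,\mathrm{TPU} - R_d,$$

with $A_n = \min(A_c, A_j, A_p)$ and ties resolved in that order. The TPU
plateau uses zero glycolate re-export, the simplest closed form; by
definition the plateau is the CO2-saturated assimilation rate
$A_{max} = 3\,\mathrm{TPU} - R_d$ reported by `amax()`.

Kinetic constants default to the 25 degC mole-fraction set of the spreadsheet
fitting tools common in this literature ($K_c = 404.9$ umol mol-1,
$K_o = 278.4$ mmol mol-1, $O = 210$ mmol mol-1). No temperature response is
modelled: the package assumes gas exchange measured at the reference
temperature, which is how cuvette campaigns at controlled 25 degC are run.
All concentrations are mole fractions internally; partial pressures are
accepted at the interface (`an_at_reference_ca()`) and converted at a fixed
101.325 kPa, since field conventions mix ppm and Pa.

Finite mesophyll conductance couples the model to the supply function
$C_c = C_i - A_n/g_m$. Substituting the supply function into each hyperbolic
branch gives a quadratic whose physical root lies on the rising branch of the
hyperbola, i.e. $C_c > -f/e$ for a branch written as
$A = a(C_c-\Gamma^*)/(eC_c+f) - R_d$; the other root sits beyond the pole and
is discarded. `solve_operating_point()` solves each branch in closed form and
applies the minimum rule afterwards; the returned pair satisfies the fixed
point to better than $10^{-9}$ relative, which the test suite asserts against
an independent bisection solve.

## Fitting CO2 response curves

`fit_aci()` estimates $V_{cmax}$, $J_{max}$, TPU and $g_m$ (with $R_d$ and
$\Gamma^*$ fixed by default at the Laisk-derived walnut values 0.73 umol m-2
s-1 and 38.18 umol mol-1) by least squares against the coupled operating
point. Two details matter:

* **Limitation partitioning.** Points sorted by $C_i$ are assigned to an
  ordered partition — a Rubisco block from the low-CO2 end, then an
  RuBP-regeneration block, then an optional TPU block — and every admissible
  partition is fitted. Parameters within a partition are estimated with
  trust-region nonlinear least squares (`minpack.lm::nls.lm`) on
  log-transformed parameters, using the smooth block-wise prediction.
  Candidates are then *scored* on the sum of squares of the full minimum-rule
  model, so a partition whose labels contradict the states its own fitted
  parameters imply cannot win on an artefact of the relaxation. Ties are
  broken by the lower $g_m$. This replaces the analyst-assigned segments of
  spreadsheet practice with a deterministic, testable rule.
* **Multistart.** The winning partition is refitted from three jittered
  starts (seeded, log-normal sd 0.3) because the $V_{cmax}$/$g_m$ objective
  has a long curved valley.

The reported limitation labels are the states the fitted parameters imply
under the minimum rule, with a $10^{-6}$ margin before a later state may
claim a point: a TPU plateau that merely touches the top point is not an
observed plateau, and `amax()` then flags its estimate as an extrapolation.

### Identifiability under noise

On noiseless self-generated curves the fit recovers all free parameters to
machine precision, and the suite asserts recovery to 0.1%. Under measurement
noise the picture changes qualitatively: with the 12-step CO2 sequence,
Gaussian noise of sd 0.3 umol m-2 s-1 on $A_n$, and walnut-scale truth
($V_{cmax}=100$, $J_{max}=150$, TPU $=9.08$, $g_m=0.2$), the Fisher
information of the curve gives Cramér–Rao relative standard deviations of
roughly 0.2 for $V_{cmax}$ and 0.5 for $g_m$ — the well-known ridge of
simultaneous $V_{cmax}$/$g_m$ estimation from a single curve. No unbiased
single-curve estimator can do better; the package's estimator tracks an
oracle fit (true partition, started at truth) closely, and the recovery study
in `scripts/acceptance.R` reports the achieved medians rather than hiding
them. TPU (hence $A_{max}$) and $J_{max}$ remain well determined. For
precise $g_m$ one should use the fluorescence route below, which is exactly
why field practice cross-validates the two; replicate averaging (n = 5 in
the intended design) tightens the curve-fit parameters accordingly.

## Mesophyll conductance from fluorescence

The variable-J chain is

$$J_{flu} = \Phi_{PSII} \cdot \mathrm{PPFD} \cdot \alpha \cdot \beta, \qquad
g_m = \frac{A_n}{C_i - \Gamma^*\dfrac{J_{flu} + 8(A_n+R_d)}{J_{flu} - 4(A_n+R_d)}}, \qquad
C_c = C_i - A_n/g_m,$$

with leaf absorbance $\alpha = 0.853$ (measured for walnut) and PSII fraction
$\beta = 0.5$ (C3 default). Preconditions are enforced as errors, never
clipped: $J_{flu} \le 4(A_n+R_d)$ or a non-positive drawdown denominator
indicate that the point is not usable (not RuBP-limited, or inconsistent
fluxes), and in real data these must be auditable rather than silently
coerced.

$\Gamma^*$ is taken equal to the intercellular photocompensation point
$C_i^*$ throughout, without a mesophyll-resistance correction — consistent
with how the calibration constants were derived.

`laisk_estimate()` recovers $(C_i^*, R_d)$ as the common intersection of
low-CO2 response lines measured at several irradiances. The paper-trail
methods in this field rarely state the numerical intersection procedure, so
the package uses a deterministic estimator that is exact in the concurrent
case: OLS lines per irradiance, all pairwise intersections, weighted mean
with weights $|b_i - b_j|$ (steep crossings locate the point precisely;
near-parallel pairs carry little weight, and exactly parallel pairs are an
error). When several curve sets exist per irradiance the package expects
$A_n$ averaged within (irradiance, $C_i$) cells before line fitting; this
averaging convention is an assumption and is stated here deliberately.

## MicroCT diffusion traits

Volumes are 3D integer label grids (`labeled_volume()`): 0 background,
1 adaxial epidermis, 2 abaxial epidermis, 3 mesophyll cell, 4 intercellular
airspace (IAS), 5 vein, 6 stomatal pore; axis 1 runs adaxial to abaxial.
Isotropic voxels only — anisotropic sizes are rejected rather than silently
rescaled, because every distance below assumes one edge length (default
0.65 um, the resolution of synchrotron leaf scans this package targets).

Voxel-count traits are exact rationals: porosity
$\theta_{IAS} = V_4/(V_3+V_4+V_5)$, the IAS:cell ratio $V_4/V_3$, and the
vein fraction $V_5/\sum V_{1..6}$. Whether the mesophyll volume in
$SA_{mes}/V_{mes}$ should include vein voxels is ambiguous in common usage;
the package includes them, consistent with the porosity denominator, and
flags the choice here. Surface area is estimated by counting cell/IAS voxel
faces; a raw mode is exact and test-friendly, while the default applies a
2/3 correction factor (a plane of random orientation is face-overcounted by
3/2 on average). The factor is configurable for users who calibrate against
a marching-cubes pipeline.

`distance_maps()` computes three fields restricted to or measured from the
airspace:

* $L_{geo}$ — geodesic distance from stomatal sources through IAS voxels,
  via multi-source Dijkstra on the 26-connected grid with chamfer weights
  $\{1, \sqrt2, \sqrt3\} \times$ voxel size. Sources are IAS voxels adjacent
  to stomatal pores; when no pores are labelled the package falls back to all
  IAS voxels touching the abaxial epidermis (a fully open lower surface). A
  volume whose abaxial side is sealed and unlabelled raises a no-stomata
  error.
* $L_{Euc}$ — exact Euclidean distance from the same sources ignoring
  obstacles (Felzenszwalb–Huttenlocher transform).
* $L_{epi}$ — Euclidean distance from the abaxial epidermis *inner surface*,
  defined as the layer of non-epidermis voxels face-adjacent to the abaxial
  epidermis. Measuring to this voxel layer (rather than into the epidermis)
  keeps $L_{Euc}$ and $L_{epi}$ on the same voxel-centre metric, so a
  continuous abaxial source sheet gives $\lambda = 1$ exactly.

Leaf-level tortuosity is $\tau_{leaf} = \overline{(L_{geo}/L_{Euc})^2}$ and
lateral path lengthening $\lambda_{leaf} = \overline{L_{Euc}/L_{epi}}$,
averaged with equal weights over IAS voxels face-adjacent to mesophyll cells
("the edge of mesophyll cells"). Patch-area weighting would be an
alternative; equal weighting was chosen and is flagged here. Voxels closer
than one voxel to a source are excluded (the 0/0 singularity at sources),
as are voxels the airspace cannot reach. The chamfer metric overestimates
true Euclidean length by up to ~7% for unfavourable directions, which is why
slab-geometry checks carry a 5% band; a fast-marching backend would reduce
this but the chamfer metric is the documented, oracle-tested primary.

The airspace conductance for hypostomatous leaves uses half the mesophyll
thickness as the gas-phase path:

$$g_{IAS} = \frac{\theta_{IAS}\, D_m}{0.5\, L_{mes}\, \tau_{leaf}\, \lambda_{leaf}},$$

with $D_m = 1.54\times10^{-5}$ m2 s-1 for CO2 in air at 25 degC. The formula
yields a velocity (m s-1); because this literature reports molar-bar units,
the package divides by the molar volume at 25 degC and 1 atm
(0.024465 m3 mol-1) and returns mol m-2 s-1 bar-1, keeping the velocity as
an attribute. Thicknesses are column-wise extents (labels 1–6 for the leaf,
3–5 for the mesophyll), averaged over paradermal columns that contain both
epidermis layers. Stomatal density counts 8-connected components of a
paradermal pore mask per field area (0.04 mm2 by convention) with a minimum
component size to suppress segmentation specks.

## Synthetic data: what it emulates and what it does not

The generators exist so that every analysis has inputs with known ground
truth, and each one is a closure: its declared truth, recomputed by the
analysis modules from its own output, matches within stated tolerances.

* `make_leaf_phantom()` builds an epidermis/palisade/spongy/vein/stoma
  geometry: cell cylinders for palisade, random cell ellipsoids for spongy
  tissue, vein cylinders, pores through the abaxial epidermis with opened
  substomatal cavities. Porosity is tuned to target by seeded flipping of
  cell/IAS boundary voxels (kept away from pore mouths so sources stay
  connected), converging within 100 iterations or failing loudly. Porosity,
  vein fraction and thicknesses are exact by construction. The phantom does
  *not* emulate real cell morphogenesis, wall curvature, light gradients, or
  segmentation error — so trait exactness on phantoms validates the
  estimators' arithmetic, not their robustness to imperfect segmentation.
* `simulate_gas_exchange()` generates curves at the 12-step CO2 sequence
  (400, 50, 80, 100, 150, 200, 400, 600, 800, 1000, 1200, 1500 umol mol-1)
  by solving $C_i$ jointly from the stomatal supply relation
  $A_n = g_s (C_a - C_i)/1.6$ and the FvCB operating point, so simulated
  curves carry the same internal consistency an instrument enforces (1.6 is
  the H2O:CO2 diffusivity ratio). $\Phi_{PSII}$ is back-computed by
  inverting the fluorescence relation from the electron transport that
  supports the modelled carboxylation plus photorespiration, which makes the
  variable-J estimator an exact algebraic inverse on noiseless points —
  the closure the tests exploit. Gaussian noise goes on $A_n$ only.
  Default light is saturating (PPFD 1500 umol m-2 s-1).
* `apply_dehydration()` emulates the anatomical response to water stress —
  thinner leaves, cells shrinking more than airspace — by removing a
  fraction of mesophyll slices and eroding cell surface voxels into IAS, so
  leaf thickness decreases and porosity strictly increases by construction.
* `make_climate_table()` produces sinusoidal monthly temperature and
  precipitation. For a 12-month sampled sinusoid with mean $m$ and amplitude
  $a$ the seasonality CV is exactly $100\,(a\sqrt{6/11})/m$ with the n−1
  SD — within ~4% of the continuous-time $100\,(a/\sqrt2)/m$ — and this
  analytic value ships as ground truth.

All randomness flows through one seeded, restored RNG scope per call; no
generator leaks global state, and identical seeds give bit-identical output.

## Study-level statistics

`seasonality_cv()` is $100 \cdot \mathrm{SD}/\mathrm{mean}$ of 12 monthly
values, computed on degC for temperature (the convention of the climate
databases this mirrors); a near-zero mean raises an error rather than
returning a meaningless number. `wue_i()` is $A_n/g_s$;
`percent_change()` is the signed percent difference from the well-watered
reference; `bonferroni_alpha()` divides the family-wise level by the number
of comparisons (0.05/25 = 0.002 in the intended design, with 0.0025 equally
expressible since the threshold is a parameter). `gias_contribution()`
expresses the gas-phase share of total mesophyll resistance as
$100\,g_m/g_{IAS}$ under a series-resistance model and refuses
$g_m > g_{IAS}$.

`dehydration_comparison()` compares replicate-level percent changes between
accessions with Welch two-sample tests at the adjusted threshold. This is a
deliberate simplification of the mixed linear models sometimes used for such
tables: the random-effects structure of those models is rarely reported and
cannot be reproduced faithfully, whereas the Welch test's operating
characteristics on replicate percent changes are verifiable by simulation
(the suite confirms both its power on a −50% vs −20% contrast at n = 5 and
the nominal size of the companion correlation test). Accession-level
correlations are computed on replicate means (n = 5 in the intended design),
with optional log/square transforms.

## Numerical choices and degenerate inputs

* Quadratic root selection in the operating point: the root with
  $C_c > -f/e$ (the hyperbola's rising branch); discriminant failure or a
  negative $C_c$ root is a hard error, not an NA.
* `nls.lm` control: maxiter 200, ftol $10^{-15}$, ptol $10^{-13}$;
  parameters fitted on the log scale to enforce positivity.
* Partition/multistart ties: lowest SSE, then lowest $g_m$, margins of
  $10^{-12}$.
* State labelling margin $10^{-6}$ (see above).
* Distance-map exclusions: voxels within one voxel of a source, unreachable
  voxels, and (for $\lambda$) voxels within one voxel of the inner surface.
* Degenerate statistics (zero-variance differences, zero-variance
  correlation columns, single replicates) return explicit flags instead of
  numbers.

## Problem sizes used by the checks

The shipped tests and the acceptance script run entirely on generated data:
phantoms between $20\times12\times12$ and $60\times40\times40$ voxels
(Dijkstra-oracle comparisons on the smaller ones), 12-point curves, 200
replicates for the noisy recovery study, 500 for the Laisk study, and 1000
null simulations for the correlation-size check. These sizes were chosen so
the whole validation runs on a laptop in about a minute while keeping the
Monte Carlo standard errors well inside the asserted bands.

## Known limitations

* No temperature responses of kinetic constants; measurements away from the
  reference temperature need external normalisation first.
* Single-curve $V_{cmax}$/$g_m$ identifiability under noise is fundamentally
  limited (see above); treat single-curve $g_m$ from `fit_aci()` as a
  cross-check on the fluorescence estimate, not a replacement.
* Segmentation is out of scope: the package consumes label volumes and its
  phantom-based validation says nothing about segmentation error.
* The phantom's geometry is schematic; absolute trait values from phantoms
  (e.g. $g_{IAS}$ of a thin synthetic slab) are internally consistent but
  not predictions for real leaves.
* Liquid-phase (cell wall, membrane, stroma) conductance modelling from
  $SA_{mes}$ is not implemented; $g_{IAS}$ covers the gas phase only.
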