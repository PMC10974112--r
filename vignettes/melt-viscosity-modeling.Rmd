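---
title: "Modeling melt viscosity of drug/polymer mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling melt viscosity of drug/polymer mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rheomelt)
library(dplyr)
```

## The model and its assumptions

`rheomelt` describes the melt viscosity of a drug/polymer mixture as a
Carreau shear-thinning curve whose effective shear rate is rescaled by two
multiplicative shift factors:

* **Carreau**: `eta(rate) = eta0 / (1 + rate/gamma_c)^c`. Valid for
  entangled polymer melts showing a Newtonian plateau followed by a
  power-law branch; it does not describe yield stresses or
  shear-thickening.
* **Arrhenius time–temperature superposition**:
  `a_T = exp[(EA/R)(1/T_K − 1/Tref_K)]`. Assumes the measurement
  temperatures sit well above the glass transition, where log shift factors
  are linear in reciprocal temperature (closer to Tg a
  Williams–Landel–Ferry form would be needed; deliberately out of scope).
* **Drug shift factor**: `a_drug = eta0(w)/eta0(0)`, modeled as
  `exp(w·s_plast)` for dissolved drug, `exp(w·s_filler)` for suspended
  solid, and `exp[w_s·s_plast + (w − w_s)·s_filler]` in the two-phase
  regime with dissolved limit `w_s(T)`. Linearity of `ln a_drug` in weight
  fraction is an empirical small-to-moderate-loading assumption (up to
  about 30 wt%); specific drug–polymer interactions can bend it, and the
  package reports residual diagnostics rather than modeling curvature.

Both shift factors act on the *rate* axis (constant-shear-stress shifting),
so the global model is
`eta = eta0·a_T·a_drug / (1 + rate·a_T·a_drug/gamma_c)^c`; with
`a_drug = 1` it reduces exactly to the Carreau–Arrhenius form. Oscillatory
frequency sweeps and rotational sweeps are identified one-to-one
(omega in rad/s with shear rate in 1/s) under the Cox–Merz rule;
`cox_merz_deviation()` measures how well that holds for a given pair of
sweeps.

## Parameters

| parameter | units | meaning | typical range |
|---|---|---|---|
| `eta0` | Pa·s | zero-shear plateau at `Tref_C` | 7×10² – 2×10⁴ |
| `gamma_c` | 1/s | shear-thinning onset | 1 – 60 |
| `c` | – | negative log-log slope of the thinning branch | 0.3 – 0.6 |
| `EA` | J/mol | activation energy of flow | 1.2×10⁵ – 1.9×10⁵ |
| `Tref_C` | °C | reference temperature | 160 by default |
| `s_plast` | – | slope of `ln a_drug` per weight fraction, dissolved drug | negative |
| `s_filler` | – | same for suspended solid | positive |

Temperatures are Celsius at every interface and converted to Kelvin only
inside the Arrhenius expression, because instrument protocols and reports
use Celsius. `EA` is treated purely as the numerator of `EA/R` with
R = 8.314 J/(mol·K); its magnitudes are consistent with J/mol even though
activation energies for these polymers are sometimes tabulated under other
unit labels. `reference_polymer_params()` ships literature parameter sets
for three common hot-melt-extrusion carriers (a butylated methacrylate
copolymer, Soluplus, and copovidone) as realistic generators and fitting
fixtures.

The filler slope is regressed on *weight* fraction for consistency with how
shift factors are plotted and used here, although classical suspension
models work in volume fraction; converting would require melt densities,
and a density-based conversion is deliberately not built in.

## Estimation choices

**Objective.** All fitting minimizes squared residuals of log10 viscosity
with equal weights: viscosities span several decades, and log-scale least
squares weights every decade of the flow curve equally.

**Algorithm.** Bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) over
(log10 eta0, log10 gamma_c, c, log10 EA). Default box constraints:
eta0 ∈ [10⁻¹, 10⁸] Pa·s, gamma_c ∈ [10⁻³, 10⁴] 1/s, c ∈ [0.01, 0.99],
EA ∈ [10³, 10⁶]. A solution at a bound triggers a warning rather than
silent acceptance.

**Initialization.** `EA` starts from the slope of `ln eta` at the lowest
measured rate against 1/T_K; curves are then provisionally reduced to the
reference temperature, `eta0` starts at the maximum reduced viscosity,
`c` at 0.4, and `gamma_c` at the reduced rate where viscosity first falls
below `eta0/2^0.4`. Two additional seeded, jittered starts guard against
local minima; the best of the three by deviance wins. Because the residual
sum is order-independent and the starts are seeded, fits are invariant to
row and replicate order and reproducible for a given seed.

**Replicate statistics.** Each replicate sweep set is fitted separately and
parameters are summarized as mean ± sd, the way triplicate rheometer runs
are reported; the pooled fit over all points is reported alongside
(`tidy()` shows both). No bootstrap or profile-likelihood uncertainty is
attempted beyond the replicate sd.

**Identifiability.** A single temperature cannot separate `EA` from `eta0`,
so `fit_carreau_arrhenius()` refuses it with an explicit error, as it does
for inputs mixing several compositions.

**Shift-factor estimation.** The superposition step minimizes, per
temperature, the mean squared log-viscosity distance between the reduced
curve and the reference curve over their overlapping reduced-rate range,
with linear interpolation in log–log coordinates (curves are log-spaced and
span decades). The search is a coarse grid over ±8 decades of shift
followed by local refinement to a 10⁻¹⁰ tolerance in log10 a; absence of
any overlap in that bracket is an error naming the offending temperature.
When no sweep sits exactly at the reference temperature, the nearest
temperature serves as reference and a warning records the substitution.
These pairwise factors can be used directly or refined implicitly by the
simultaneous fit, which re-estimates `EA` from all points at once.

**Slope regression.** `fit_shift_slope()` regresses `ln a_drug` on `w`
through the origin, because `a_drug(0) = 1` holds by construction of the
reference; opaque (suspected two-phase) observations are excluded and
counted.

**Solubility extraction.** For an over-loaded formulation the observed
shift factor at each temperature is inverted algebraically:
`w_s = (ln a − w·s_filler)/(s_plast − s_filler)`, the intersection of the
plasticizing line with the filler line translated through the observed
point. Equal slopes make the geometry degenerate and raise an error.
Results are clamped to [0, w] with a warning: rheology cannot see dissolved
fractions above the total drug load, so at temperatures where the true
solubility exceeds `w` the method returns the saturation value `w` — any
comparison against a generating curve must clamp it the same way.

## The synthetic-data generator

`sweep_design()` defaults emulate a standard oscillatory campaign:
0.628–628 rad/s at 10 points per decade (31 rates), 130–200 °C in 10 K
steps, triplicates, reference temperature 160 °C, and multiplicative
log-normal noise with sigma = 0.02. The noise model is multiplicative
because replicate scatter on log-log flow curves of melt rheometers is
small and roughly proportional; sigma = 0.02 makes triplicates nearly
coincide on a log axis, as they do on real instruments. Rotational designs
are truncated above 10 1/s, where plate–plate gap emptying ends the usable
range. Generation is deterministic given the design seed and leaves the
caller's random stream untouched.

The generator does **not** emulate: temperature errors or drift, instrument
inertia/compliance artifacts, amplitude-sweep nonlinearity (the 1 %
deformation amplitude of a linear-viscoelastic protocol is metadata, not a
simulated process), thermal degradation, or slow dissolution kinetics.
Passing round-trip tests therefore demonstrates the correctness of the
estimation machinery under the model's own assumptions — not robustness to
every artifact of real melts. In particular, real two-phase systems
equilibrate slowly, so rheology-derived solubilities at low temperature can
sit off the equilibrium phase boundary; no kinetic correction is applied.

## Degenerate inputs and numerical details

* `solubility_at()` interpolates the tabulated phase boundary piecewise
  linearly and refuses extrapolation, since boundaries bend sharply near
  the glass transition; the two-phase prediction is continuous in
  temperature across the full-dissolution point.
* `w_s` is clamped to `w_drug` inside the two-phase shift factor — the
  dissolved fraction cannot exceed the total.
* Constant-stress reduction conserves `rate × viscosity` exactly, which the
  tests assert to machine precision.
* Master-curve collapse quality (`glance()` on a master curve) is the mean
  within-bin sd of log10 viscosity around a local linear trend (5 bins per
  decade), so flow-curve curvature does not masquerade as scatter; for
  model-generated data it is bounded by the injected noise.
* The zero-shear comparison between two formulations is a Welch t test on
  per-replicate `eta0` estimates at a user-set alpha (default 0.05).

## Problem sizes

The test suite and the acceptance script run at the study scale: 31-point
sweeps, 8 temperatures, triplicates (744 points per system), with fits
taking well under a second each. Law-of-large-numbers checks of the noise
model use 1000 replicates of a reduced 4-point sweep.

## Known limitations

Single Arrhenius branch (no WLF), no vertical density shifts, no
storage/loss modulus decomposition, linear `ln a_drug(w)` only, solubility
curve as user input (no Flory–Huggins/PC-SAFT fitting), and replicate sd as
the only uncertainty measure. These bounds mirror the intended use: fast
parameterization of processing-relevant viscosity from a handful of
rheometer runs.
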