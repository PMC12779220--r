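---
title: "Measuring and designing oxygen transport in cell-laden hydrogels"
author: "oxydiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and designing oxygen transport in cell-laden hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxydiff)
```

## The problem

Hydrogels such as alginate are used to immobilize mammalian cells — notably
insulin-producing beta cells in encapsulation therapies for diabetes. The gel
suppresses bulk fluid motion, so oxygen reaches the cells by diffusion alone,
and the oxygen diffusion coefficient of the material becomes the controlling
transport parameter. It is rarely measured; most device models assume a
literature value. `oxydiff` implements a complete desk workflow around a
simple measurement rig — an optode needle probe in a sealed Petri dish whose
headspace gas can be switched from air to nitrogen — covering:

1. a **forward model** of one-dimensional transient oxygen diffusion through
   one or two layers (gel plus top-up medium) with a realistic boundary
   response at the gas/liquid interface;
2. an **estimator** that recovers the diffusion coefficient of a layer from
   the recorded probe trace by minimizing the mean absolute percent error
   (MAPE) between model and data;
3. a **design framework** for immobilized-cell systems under zero-order
   oxygen consumption: Thiele modulus, effectiveness factor, viable-front
   depth, and thickness-versus-cell-density design curves.

## Units and constants

Internally everything is SI: metres, seconds, mol m⁻³. Diffusion
coefficients cross the interface in cm² s⁻¹ because that is how the field
reports them; oxygen levels may enter as `% air saturation` (the optode
readout), `mmHg`, or `mol m⁻³`. The conversion chain is linear at the fixed
37 °C set point:

* `mmHg → mol m⁻³` through a solubility of 1.2 × 10⁻³ mol m⁻³ mmHg⁻¹, the
  value that makes 25 mmHg correspond to 0.03 mol m⁻³ in dilute aqueous
  media at 37 °C. Literature Henry constants at this temperature span
  roughly 1.2–1.35 × 10⁻³, so the registry value is configurable.
* `% air saturation → mmHg` through the dry-air O₂ fraction (0.2095) of the
  humidified pressure head (760 − 47 mmHg at 37 °C). This unit is defined by
  the optode two-point calibration against air-saturated water; it is
  distinct from an incubator gas-mix percentage such as "18.6 % O₂", which
  is a mole fraction of the gas phase.

All constants live in one immutable registry (`o2_constants()`), overridable
per call or through the `constants:` section of a YAML configuration, so a
single object pins down every conversion in an analysis.

Temperature-dependent solubility or diffusivity correlations and salinity
corrections are out of scope: the rig operates at one set point.

## The forward model

The governing equation is Fick's second law in one spatial dimension,

$$\frac{\partial C}{\partial t} = \frac{\partial}{\partial z}
\left( D(z) \frac{\partial C}{\partial z} \right),$$

on a stack of one layer (4 mm of liquid, the validation geometry) or two
layers (3.5 mm of gel under 1.5 mm of top-up medium). The dish bottom is
glass, whose oxygen permeability is orders of magnitude below any aqueous
phase, so `z = 0` carries a zero-flux condition. The top surface follows a
**boundary driver**:

* `constant` — equilibrium control;
* `ideal_step` — an instantaneous switch, useful for analytic work;
* `fopdt` — first-order-plus-dead-time, the empirically observed interface
  response to an inlet gas switch: dead time θ = 3 s, time constant
  τ = 23 s by default. With these values the interface reaches 1 % of its
  initial level in θ + τ ln 100 ≈ 1.8 min, negligible against the 1–2 h
  duration of a depletion experiment — which is what justifies treating the
  switch as a boundary condition rather than modelling the headspace.

Advection is neglected by design. The Péclet number `Pe = uL/D` of the
headspace-driven flow is below unity at the operating gas flow rate;
`peclet()` computes the check but takes the interface velocity as an input —
resolving the flow field is a CFD problem outside this package's scope.

### Discretization

The solver uses finite volumes with nodes uniformly spaced inside each layer
(default 20 µm) and layer interfaces placed exactly on nodes, so each
inter-node edge lies within a single material and interfacial continuity of
concentration and flux holds by construction (partition coefficient 1).
Time stepping is Crank–Nicolson (default 0.5 s), unconditionally stable over
multi-hour horizons; the march itself is compiled code. Probe sampling
interpolates linearly between the bracketing nodes at the probe height
(default 1.8 mm above the dish bottom, the needle-tip offset of the rig).

Numerical safeguards: requested output times are interpolated between time
levels; round-off negatives are clamped to zero and a warning is raised only
if they exceed 10⁻⁹ of the initial concentration; with a sealed top the
scheme conserves mass to round-off, which the test suite asserts at 10⁻¹⁰
relative over 1000 steps.

### Verification

An independent cosine-series solution for the single-layer step problem,

$$\frac{C}{C_0} = \sum_{n \ge 0} \frac{4(-1)^n}{(2n+1)\pi}
\cos\!\left(\frac{(2n+1)\pi z}{2H}\right)
\exp\!\left(-\frac{(2n+1)^2\pi^2 D t}{4H^2}\right),$$

is implemented as `analytic_single_layer()` and the solver is required to
track it within 0.5 % of C₀ for Fourier numbers `Dt/H² > 0.005` at default
resolution. Halving both grid spacing and time step must move the
probe-height solution by less than 0.2 % of C₀. Both contracts are enforced
in the tests.

There is one genuine geometric ambiguity in the rig description: 4 mm is the
liquid height (and the Péclet length scale) while 3.5 mm is the gel height
in the two-layer configuration. Both presets are provided
(`geometry_preset("water")`, `geometry_preset("gel")`) rather than resolving
the inconsistency.

## The estimator

`fit_diffusion()` minimizes

$$\mathrm{MAPE}(D) = \frac{100}{N} \sum_i
\frac{|m_i(D) - o_i|}{\max(o_i,\ \varepsilon C_0)}$$

over the diffusivity of one target layer, using Brent's bounded scalar
method on log₁₀ D (default bounds 10⁻⁶–10⁻⁴ cm² s⁻¹, relative tolerance
10⁻³). Two choices the raw MAPE definition leaves open are fixed as
follows, because percent errors degenerate as readings approach zero during
a purge:

* the **fit window** runs from the step onset to the first time the
  observed trace drops below 1 % of its initial value (or the trace end);
* the **denominator floor** is ε = 0.02 of the initial value.

MAPE is computed on concentrations in a common unit (the package converts
to mol m⁻³ first); since the objective is relative, the estimate is
invariant to the recording unit, which the tests assert. When fitting the
gel layer of a two-layer stack, the medium layer is held at the diffusivity
of water at 37 °C; joint multi-parameter fitting (θ, τ and D together) is
deliberately not offered — one unknown, one trace.

An optimum within tolerance of a search bound sets `converged = FALSE`
rather than being returned silently. Replicate fits are summarized by
`aggregate_replicates()` (mean, sample SD, SEM).

Because no raw bench traces ship with the package, the estimator's accuracy
is established by **parameter recovery**: traces manufactured by the forward
model at known D (noise-free and with 1 % Gaussian read noise) are refit and
the recovered values compared with the embedded truth. Noise-free recovery
is required to land within 1 % of truth across 1–4 × 10⁻⁵ cm² s⁻¹ on both
geometries, and the 20-seed noisy mean within 3 %.

## The synthetic-data generator

`synthetic_spec()` / `generate_trace()` emulate a logger export: a forward
solve at the probe height over 2 h, sampled every 5 s, plus independent
additive Gaussian noise with SD proportional to the initial concentration
(1 % of C₀ when enabled — an assumption, exposed as a parameter, since probe
noise is not otherwise characterized). Seeds are mandatory and recorded in
the trace metadata together with the full ground truth; the global RNG
stream is never touched. Three named fixtures exist: `water_37C`
(D = 3.1 × 10⁻⁵ cm² s⁻¹, the textbook value for water at 37 °C) and
`gel_2pct` / `gel_5pct`, whose gel diffusivities (2.4 and
1.6 × 10⁻⁵ cm² s⁻¹) are **synthetic placeholders** that exist to exercise
the two-layer code path, not measured values.

What the generator does *not* emulate — and therefore what passing recovery
tests do not establish about bench data: probe response lag, optode
photobleaching and drift, autocorrelated noise, temperature excursions,
radial diffusion in stiff gels (a real effect: early-time responses of
high-concentration gels lag a 1D model), and advection in low-viscosity
samples.

## The design framework

For a slab of thickness L seeded at cell volume fraction X, oxygen is
consumed at the zero-order volumetric rate `k_v = X · OCR` wherever the
local concentration exceeds a critical level `C_crit`. Zero-order kinetics
are appropriate because the Michaelis constant of beta cells
(≈ 0.44 mmHg) is far below the oxygen tensions of interest. Cells below
`C_crit` die and stop consuming, producing the classical obstacle problem
with a sharp viable front at

$$x_v = \sqrt{\frac{2\,D_\mathrm{eff}\,(C_s - C_\mathrm{crit})}{k_v}},$$

where both the concentration excess and the flux vanish (smooth pasting).
The alternative — consumption continuing to exhaustion — admits negative
concentrations and is rejected. `C_crit` defaults to the concentration
equivalent of 0.1 mmHg (≈ 1.2 × 10⁻⁴ mol m⁻³), the threshold at which
live/dead boundaries are observed; it is numerically negligible in the
effectiveness formulas, and whether tabulated effectiveness values used 0
or 0.1 mmHg is indistinguishable at two decimals.

The effective diffusivity is the cell-fraction-weighted mixture
`D_eff = X·D_tissue + (1−X)·D_material`, with tissue at
1.24 × 10⁻⁵ cm² s⁻¹. Cell counts convert to volume fractions through a
default single-cell volume of 1.7 pL (a typical beta-cell scale,
configurable — the count-to-fraction conversion is otherwise
unconstrained).

Dimensionless form: the zero-order Thiele modulus is

$$\varphi = L \sqrt{\frac{X \cdot \mathrm{OCR}}{D_\mathrm{eff} C_s}},$$

and the slab effectiveness factor — derivable in three lines from the
parabolic viable-zone profile, and equal to the viable fraction `x_v/L` —
is

$$\eta = \begin{cases} 1 & \varphi \le \varphi_c \\
\sqrt{2\,(1 - C_\mathrm{crit}/C_s)}\,/\,\varphi & \varphi > \varphi_c
\end{cases},
\qquad \varphi_c = \sqrt{2\,(1 - C_\mathrm{crit}/C_s)}.$$

The identity `η·φ = φ_c` above the critical modulus, the continuity at
`φ_c`, and the agreement of `x_v/L` with `η` are asserted by brute force
over dense parameter grids in the tests. Tabulated effectiveness values in
this field are conventionally *truncated* to two decimals, so
`trunc_decimals()` is provided (0.5257 reports as 0.52).

### Surface coupling

The gel surface does not see the incubator atmosphere directly: oxygen
crosses a stagnant top-up medium layer first. At steady state the flux
through the medium balances the areal consumption of the viable zone,
giving the fixed point

$$C_s = C_\mathrm{amb} - k_v \min(x_v(C_s), L)\, \frac{h_\mathrm{med}}{D_\mathrm{med}}.$$

This is an explicit 1D reconstruction of the coupling (lateral losses are
ignored); it is solved by root bracketing to 10⁻⁸ relative tolerance, and
a `status` field reports `"oxygen_starved"` when the balance pins the
surface essentially at the critical concentration. A fixed point always
exists because the areal consumption vanishes as `C_s` approaches
`C_crit`; monotonicity of `C_s` in X is checked by sweep. The coupling can
be switched off by supplying `C_s` directly, which is also how tabulated
φ/η values are reproduced. Supporting this reconstruction: at fixed
everything else, φ scales as √X, so φ ratios between cell densities are
insensitive to the coupling — the tabulated ratios match √(10/1.2) within
0.5 %.

`design_thickness()` inverts the front formula: since `x_v` does not depend
on L, the thickness achieving a target effectiveness is simply
`L = x_v/η_target`, and mapping over a cell-density grid yields the design
curve (log-log slope exactly −1/2 when `C_s` is fixed). A worked sizing
example needs the material diffusivity, the surface-coupling mode and the
cell volume, none of which are universal constants; all three are explicit
arguments.

### Independent verification

`steady_profile_fd()` solves the same steady obstacle problem by projected
SOR on the finite-difference complementarity system — no closed form
anywhere in the path — and must agree with the analytic front within one
grid cell and with the profile within 1 % of `C_s` across a 3×3×3 parameter
sweep. A cross-module test also runs the *transient* solver with the masked
zero-order sink to its long-time limit and requires the profile to match
the steady closed form within 1 % of `C_s`. The depth coordinate of the
steady module runs downward from the gel surface, opposite to the transient
module's height above the dish bottom; `depth_to_height()` converts, and
the cross-module test exercises the flip.

## Problem sizes and runtimes

The package's own test battery uses coarsened solver settings (50 µm / 2 s)
and 1 h traces for the many unit-level recovery checks, and the full default
resolution (20 µm / 0.5 s, 2 h traces, 5 s sampling) for the end-to-end
acceptance battery: noise-free recovery at four diffusivities on both
geometries plus a 20-seed noisy recovery study. These sizes were chosen so
the whole suite completes in a few minutes on a laptop core while the
acceptance checks still run at the exact study conditions.

## Known limitations

* One spatial dimension; radial effects in stiff gels are real and
  unmodelled.
* Zero-order kinetics only; no Michaelis–Menten or first-order option.
* Slab geometry only; no cylinder or sphere effectiveness factors.
* No oxygen sources (oxygen-generating materials are out of scope).
* The noise model is white and Gaussian; real optode noise is not.
* The surface-coupling model is a 1D flux balance; a full 2D treatment of
  the medium layer would differ near the dish walls.
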