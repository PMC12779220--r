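# oxydiff

Oxygen transport in cell-laden hydrogels: measure it, then design around it.

Hydrogel-immobilized cells — alginate-encapsulated pancreatic beta cells
being the motivating case — receive oxygen by diffusion alone, and the
oxygen diffusion coefficient of the gel is the parameter that decides
whether cells deep in a device live or die. `oxydiff` is an R package for
the complete desk side of a simple measurement-and-design workflow:

* **Forward model** — 1D transient diffusion (Fick's second law) through a
  one- or two-layer stack (gel + top-up medium) on a glass dish bottom
  (zero flux), driven at the top surface by a first-order-plus-dead-time
  (FOPDT) gas-switch response (θ = 3 s, τ = 23 s by default).
  Crank–Nicolson finite volumes with interfaces on grid nodes; compiled
  core; verified against an independent cosine-series solution.
* **Estimator** — `fit_diffusion()` recovers a layer's diffusivity D from
  an optode probe trace by bounded minimization of the mean absolute
  percent error (MAPE) between model and data. Returns a classed
  `diffusion_fit` object with `print`, `summary`, `coef`, `predict`,
  `fitted`, `residuals`, `plot` and `simulate` methods.
* **Design framework** — zero-order reaction–diffusion in a slab seeded at
  cell fraction X consuming at rate k_v = X·OCR: viable-front depth
  x_v = √(2 D_eff (C_s − C_crit)/k_v), Thiele modulus
  φ = L √(X·OCR/(D_eff C_s)), effectiveness factor
  η = min(1, √(2(1 − C_crit/C_s))/φ), surface-concentration coupling
  through the medium layer, and thickness-versus-cell-density design
  curves.
* **Synthetic data** — seed-fixed trace generation with embedded ground
  truth, so estimator accuracy is established by parameter recovery.
* **I/O and CLI** — delimited trace parsing with explicit column/unit
  mapping, JSON/CSV results with settings hashes, a YAML configuration
  format, and a command-line wrapper (`inst/cli/oxydiff`) with `synth`,
  `fit`, `simulate`, `viability`, `design` and `report` subcommands.

## Worked example

Manufacture a noisy 2-hour water-validation trace, refit it, and size an
encapsulation slab:

```r
library(oxydiff)

# synthetic probe trace: 4 mm water column, N2 purge, 1% read noise
spec <- make_fixture("water_37C", noise_sd = 0.01, seed = 42)
obs  <- generate_trace(spec)

fit <- fit_diffusion(obs, spec$stack, spec$driver)
fit
#> Oxygen diffusion coefficient fit (MAPE minimization)
#>   D_hat     = 3.123e-05 cm^2/s
#>   MAPE      = 7.33 %  (14 model evaluations)
#>   window    = [0, 7200] s
```

The fixture's true diffusivity is 3.1 × 10⁻⁵ cm² s⁻¹ (water at 37 °C); the
estimate lands within 1 % despite the 1 % read noise. The MAPE of 7.3 %
reflects the noise level relative to the floored denominators, not a model
misfit — refitting the noise-free trace gives an objective of 0.012 %.

```r
# dimensionless screening of a seeded slab (surface concentration supplied)
dimensionless_report(L_mm = 3.5, X = cells_to_fraction(1.2e6), OCR = 0.129,
                     D_material_cm2_s = 2.4e-5, C_s = 0.15)
#> Dimensionless transport report:
#>   Pe       = 0 (diffusion dominated)
#>   phi      = 2.99 (phi_crit = 1.41)
#>   eta      = 0.472
```

φ above its critical value √2 means the slab interior is oxygen-limited:
only 47 % of the seeded cells sit above the lethal threshold. The thickness
that would keep 90 % of cells viable at this density:

```r
design_thickness(cells_to_fraction(1.2e6), 0.9, OCR = 0.129,
                 D_material_cm2_s = 2.4e-5, C_s = 0.15,
                 couple_surface = FALSE)$L_mm
#> [1] 1.836225
```

i.e. 1.8 mm rather than 3.5 mm. `design_curve()` maps this over a
cell-density grid; `predict_viable_fraction()` additionally couples the
surface concentration to the cell fraction through the top-up medium layer.

See the vignette (`vignettes/oxygen-transport.Rmd`) for the model
assumptions, parameter defaults, numerical choices and limitations.

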