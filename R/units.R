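#' Physical constants and unit system for oxygen transport calculations
#'
#' `o2_constants()` builds the immutable registry of physical constants used
#' throughout the package. Every other function takes such a registry (or
#' builds the default), so a single configuration governs all unit
#' conversions, boundary drivers and design formulas.
#'
#' All concentrations are held internally in SI (mol m^-3); diffusion
#' coefficients are accepted and reported in cm^2 s^-1 because that is the
#' unit the field reports. The default oxygen solubility, 1.2e-3
#' mol m^-3 mmHg^-1, reproduces the 25 mmHg ~ 0.03 mol m^-3 correspondence
#' that holds at 37 degrees C in dilute aqueous media; literature Henry
#' constants at 37 degrees C span roughly 1.2--1.35e-3, so the value is
#' configurable.
#'
#' @param ... named overrides of the default constants (see Details).
#'
#' @details Registry fields (all overridable):
#' \describe{
#'   \item{solubility}{oxygen solubility, mol m^-3 mmHg^-1 (default 1.2e-3)}
#'   \item{D_water_37C}{oxygen diffusivity of water at 37 C, cm^2 s^-1
#'     (default 3.1e-5)}
#'   \item{D_tissue}{oxygen diffusivity of tissue, cm^2 s^-1 (default 1.24e-5)}
#'   \item{OCR_MIN6}{volumetric oxygen consumption of MIN6 cells at unit cell
#'     fraction, mol m^-3 s^-1 (default 0.129)}
#'   \item{OCR_islet}{same for human islets (default 0.034)}
#'   \item{pO2_crit}{critical oxygen tension below which cells die, mmHg
#'     (default 0.1)}
#'   \item{ambient_O2_fraction}{O2 fraction of the incubator gas mix
#'     (default 0.186)}
#'   \item{total_pressure}{total pressure, mmHg (default 760)}
#'   \item{water_vapor_pressure_37C}{water vapour pressure at 37 C, mmHg
#'     (default 47); set to 0 for a dry atmosphere}
#'   \item{theta_boundary}{dead time of the gas boundary response, s
#'     (default 3)}
#'   \item{tau_boundary}{time constant of the gas boundary response, s
#'     (default 23)}
#'   \item{cell_volume_default}{single-cell volume for cell-count to
#'     volume-fraction conversion, pL (default 1.7)}
#' }
#'
#' @return An object of class `o2_constants` (a locked named list).
#' @examples
#' cst <- o2_constants()
#' convert_oxygen(o2(25, "mmHg"), "mol_m3", cst)
#' @export
o2_constants <- function(...) {
  defaults <- list(
    solubility = 1.2e-3,
    D_water_37C = 3.1e-5,
    D_tissue = 1.24e-5,
    OCR_MIN6 = 0.129,
    OCR_islet = 0.034,
    pO2_crit = 0.1,
    ambient_O2_fraction = 0.186,
    total_pressure = 760,
    water_vapor_pressure_37C = 47,
    theta_boundary = 3,
    tau_boundary = 23,
    cell_volume_default = 1.7
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  if (length(over)) {
    bad <- setdiff(names(over), names(defaults))
    if (length(bad))
      stop("unknown constant(s): ", paste(bad, collapse = ", "), call. = FALSE)
    defaults <- modifyList(defaults, over)
  }
  strict <- setdiff(names(defaults),
                    c("ambient_O2_fraction", "water_vapor_pressure_37C"))
  for (nm in strict)
    if (!is.numeric(defaults[[nm]]) || defaults[[nm]] <= 0)
      stop("constant '", nm, "' must be strictly positive", call. = FALSE)
  for (nm in c("ambient_O2_fraction", "water_vapor_pressure_37C"))
    if (!is.numeric(defaults[[nm]]) || defaults[[nm]] < 0)
      stop("constant '", nm, "' must be non-negative", call. = FALSE)
  if (defaults$water_vapor_pressure_37C >= defaults$total_pressure)
    stop("water vapour pressure must be below total pressure", call. = FALSE)
  structure(defaults, class = "o2_constants")
}

#' @export
print.o2_constants <- function(x, ...) {
  cat("Oxygen transport constants (37 C set point):\n")
  for (nm in names(x)) cat(sprintf("  %-26s %g\n", nm, x[[nm]]))
  invisible(x)
}

# registry immutability: assignment into the registry is rejected
#' @export
`$<-.o2_constants` <- function(x, name, value) {
  stop("o2_constants registries are immutable; build a new one with o2_constants()",
       call. = FALSE)
}
#' @export
`[[<-.o2_constants` <- function(x, i, value) {
  stop("o2_constants registries are immutable; build a new one with o2_constants()",
       call. = FALSE)
}

.o2_units <- c("percent_air_saturation", "mmHg", "mol_m3")

#' Tagged oxygen amount
#'
#' A value with an explicit oxygen unit tag. Supported tags:
#' `"percent_air_saturation"` (optode readout relative to air-saturated water
#' at calibration), `"mmHg"` (partial pressure), `"mol_m3"` (dissolved
#' concentration).
#'
#' @param value numeric, non-negative (vectors allowed).
#' @param unit one of `"percent_air_saturation"`, `"mmHg"`, `"mol_m3"`.
#' @return An `o2_amount` object.
#' @examples
#' o2(100, "percent_air_saturation")
#' @export
o2 <- function(value, unit = "mol_m3") {
  unit <- match.arg(unit, .o2_units)
  if (!is.numeric(value) || any(!is.finite(value)))
    stop("oxygen value must be finite numeric", call. = FALSE)
  if (any(value < 0))
    stop("oxygen value must be non-negative", call. = FALSE)
  structure(list(value = as.numeric(value), unit = unit), class = "o2_amount")
}

#' @export
print.o2_amount <- function(x, ...) {
  lab <- c(percent_air_saturation = "% air sat.", mmHg = "mmHg",
           mol_m3 = "mol/m^3")[x$unit]
  cat(format(x$value), lab, "\n")
  invisible(x)
}

# mmHg carried by 100 % air saturation at calibration: dry-air O2 fraction
# 0.2095 of the humidified pressure head. This is distinct from the
# incubator gas-mix fraction (ambient_O2_fraction).
.mmHg_per_100pct <- function(registry) {
  0.2095 * (registry$total_pressure - registry$water_vapor_pressure_37C)
}

#' Convert an oxygen amount between units
#'
#' Conversions are linear and bijective for a fixed registry:
#' mmHg to mol m^-3 through the solubility; % air saturation to mmHg through
#' the dry-air O2 fraction (0.2095) of the humidified pressure head.
#'
#' @param x an [o2()] amount.
#' @param target_unit unit tag to convert to.
#' @param registry an [o2_constants()] registry.
#' @return An `o2_amount` in `target_unit`.
#' @examples
#' convert_oxygen(o2(25, "mmHg"), "mol_m3")  # ~0.03 mol/m^3
#' @export
convert_oxygen <- function(x, target_unit, registry = o2_constants()) {
  if (!inherits(x, "o2_amount")) stop("x must be an o2() amount", call. = FALSE)
  target_unit <- match.arg(target_unit, .o2_units)
  stopifnot(inherits(registry, "o2_constants"))
  mmHg <- switch(x$unit,
    mmHg = x$value,
    mol_m3 = x$value / registry$solubility,
    percent_air_saturation = x$value / 100 * .mmHg_per_100pct(registry)
  )
  out <- switch(target_unit,
    mmHg = mmHg,
    mol_m3 = mmHg * registry$solubility,
    percent_air_saturation = mmHg / .mmHg_per_100pct(registry) * 100
  )
  o2(out, target_unit)
}

#' Ambient dissolved-oxygen concentration of the incubator atmosphere
#'
#' The gas mix above the top-up medium carries `ambient_O2_fraction` of the
#' humidified pressure head (total pressure minus water vapour at 37 C);
#' multiplying by the solubility gives the dissolved concentration a medium
#' surface in equilibrium with that atmosphere attains.
#'
#' @param registry an [o2_constants()] registry.
#' @return An `o2_amount` in mol m^-3.
#' @examples
#' ambient_concentration()  # ~0.159 mol/m^3 for an 18.6% O2 mix
#' @export
ambient_concentration <- function(registry = o2_constants()) {
  stopifnot(inherits(registry, "o2_constants"))
  pO2 <- registry$ambient_O2_fraction *
    (registry$total_pressure - registry$water_vapor_pressure_37C)
  o2(registry$solubility * pO2, "mol_m3")
}

#' Volume of a cylindrical slab
#'
#' Convenience helper for sizing gel casts: the volume of a cylinder of the
#' given diameter and height, reported in mL.
#'
#' @param diameter_mm cylinder diameter, mm.
#' @param height_mm cylinder height, mm.
#' @return Volume in mL.
#' @examples
#' slab_volume(50, 4)  # ~7.9 mL
#' @export
slab_volume <- function(diameter_mm, height_mm) {
  stopifnot(diameter_mm > 0, height_mm > 0)
  pi * (diameter_mm / 2)^2 * height_mm / 1000
}
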