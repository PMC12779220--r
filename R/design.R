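#' Peclet number
#'
#' `Pe = u L / D`, the ratio of advective to diffusive mass transport.
#' Pe < 1 indicates diffusion dominance, the condition under which the 1D
#' diffusion model of this package is valid. The interface velocity `u` is
#' an input (e.g. from a CFD model of the headspace); this package does not
#' compute it.
#'
#' @param u interface speed, m s^-1 (>= 0).
#' @param L_mm characteristic length, mm.
#' @param D_cm2_s diffusivity, cm^2 s^-1.
#' @return Pe with attribute `"diffusion_dominated"` (TRUE iff Pe < 1).
#' @examples
#' peclet(1e-6, 4, 3.1e-5)
#' @export
peclet <- function(u, L_mm, D_cm2_s) {
  stopifnot(L_mm > 0, D_cm2_s > 0)
  if (u < 0) stop("u is a speed and must be >= 0", call. = FALSE)
  pe <- u * (L_mm * 1e-3) / (D_cm2_s * 1e-4)
  structure(pe, diffusion_dominated = pe < 1)
}

#' Convert a cell concentration to a volume fraction
#'
#' `X = n * V_cell`, with the count per mL and the single-cell volume in pL.
#'
#' @param n_per_mL cell concentration, cells mL^-1.
#' @param V_cell_pL single-cell volume, pL (default 1.7, a typical beta-cell
#'   scale).
#' @return Volume fraction X in [0, 1).
#' @examples
#' cells_to_fraction(1.2e6)  # 2.04e-3
#' @export
cells_to_fraction <- function(n_per_mL, V_cell_pL = 1.7) {
  stopifnot(all(n_per_mL >= 0), V_cell_pL >= 0)
  X <- n_per_mL * V_cell_pL * 1e-9   # pL per mL = 1e-9
  if (any(X >= 1))
    stop("cell fraction >= 1 is unphysical packing", call. = FALSE)
  X
}

#' Effective oxygen diffusivity of a cell-laden gel
#'
#' Cell-fraction-weighted average:
#' `D_eff = X * D_tissue + (1 - X) * D_material`.
#'
#' @param X cell volume fraction in [0, 1].
#' @param D_tissue_cm2_s tissue diffusivity, cm^2 s^-1.
#' @param D_material_cm2_s acellular material diffusivity, cm^2 s^-1.
#' @return D_eff, cm^2 s^-1.
#' @export
effective_diffusivity <- function(X, D_tissue_cm2_s, D_material_cm2_s) {
  if (any(X < 0 | X > 1)) stop("X must lie in [0, 1]", call. = FALSE)
  X * D_tissue_cm2_s + (1 - X) * D_material_cm2_s
}

#' Thiele modulus of a zero-order slab
#'
#' `phi = L * sqrt(X * OCR / (D_eff * C_s))`: the ratio of the zero-order
#' reaction rate to the diffusive supply rate. Large phi means oxygen cannot
#' reach the depth of the slab before being consumed.
#'
#' @param L_mm slab thickness, mm.
#' @param X cell volume fraction (>= 0).
#' @param OCR volumetric consumption at X = 1, mol m^-3 s^-1.
#' @param D_eff_cm2_s effective diffusivity, cm^2 s^-1.
#' @param C_s surface oxygen concentration, mol m^-3 (> 0).
#' @return phi (dimensionless; 0 when X = 0).
#' @examples
#' thiele_modulus(1, 1, 4e-4, 1e-5, 0.1)  # 2
#' @export
thiele_modulus <- function(L_mm, X, OCR, D_eff_cm2_s, C_s) {
  stopifnot(L_mm > 0, X >= 0, OCR > 0, D_eff_cm2_s > 0)
  if (C_s <= 0) stop("C_s must be > 0", call. = FALSE)
  (L_mm * 1e-3) * sqrt(X * OCR / (D_eff_cm2_s * 1e-4 * C_s))
}

#' Effectiveness factor of a zero-order slab
#'
#' Fraction of the diffusion-unlimited consumption actually achieved, equal
#' to the viable fraction of the slab:
#' `eta = 1` for `phi <= phi_crit`, else
#' `eta = sqrt(2 (1 - C_crit/C_s)) / phi`, with
#' `phi_crit = sqrt(2 (1 - C_crit/C_s))`. Continuous at `phi_crit`, and
#' algebraically identical to `x_v / L` from [viable_depth()] in the front
#' regime (the identity is exercised in the test suite by brute force).
#'
#' @param phi Thiele modulus (>= 0, vectorized).
#' @param c_ratio `C_crit / C_s` in [0, 1).
#' @return eta in [0, 1].
#' @examples
#' effectiveness_factor(2.31)          # 0.6122...
#' trunc_decimals(effectiveness_factor(2.31), 2)  # 0.61
#' @export
effectiveness_factor <- function(phi, c_ratio = 0) {
  if (any(phi < 0)) stop("phi must be >= 0", call. = FALSE)
  if (c_ratio < 0 || c_ratio >= 1)
    stop("c_ratio must lie in [0, 1)", call. = FALSE)
  phi_crit <- sqrt(2 * (1 - c_ratio))
  ifelse(phi <= phi_crit, 1, phi_crit / phi)
}

#' Truncate (not round) to a number of decimals
#'
#' Tabulated effectiveness factors in this field are conventionally
#' truncated; 0.5257 reports as 0.52.
#'
#' @param x numeric.
#' @param digits decimals kept.
#' @return Truncated values.
#' @export
trunc_decimals <- function(x, digits = 2) {
  trunc(x * 10^digits) / 10^digits
}

#' Slab thickness achieving a target effectiveness factor
#'
#' In the front regime the viable depth `x_v = sqrt(2 D_eff (C_s - C_crit)
#' / k_v)` does not depend on the slab thickness, so the thickness that
#' yields effectiveness `eta_target` is simply `L = x_v / eta_target`. The
#' surface concentration is either supplied (`couple_surface = FALSE`) or
#' computed from the medium-layer flux balance (`couple_surface = TRUE`,
#' see [surface_concentration()]; the designed slab is at least as thick as
#' the viable zone, so the areal consumption is `k_v * x_v`).
#'
#' @param X cell volume fraction (> 0).
#' @param eta_target target effectiveness in (0, 1].
#' @param OCR volumetric consumption at X = 1, mol m^-3 s^-1.
#' @param D_material_cm2_s acellular gel diffusivity, cm^2 s^-1.
#' @param D_tissue_cm2_s tissue diffusivity, cm^2 s^-1 (default from the
#'   registry).
#' @param C_s surface concentration, mol m^-3 (used when `couple_surface`
#'   is FALSE).
#' @param C_crit_mol_m3 critical concentration, mol m^-3 (default: registry
#'   0.1 mmHg equivalent).
#' @param couple_surface couple C_s to X through the medium layer?
#' @param h_med_mm,D_med_cm2_s,C_amb medium layer and ambient parameters
#'   (used when coupling).
#' @param registry an [o2_constants()] registry.
#' @return A list: `L_mm`, `x_v_mm`, `C_s`, `phi`, `status`.
#' @examples
#' design_thickness(1e-3, 0.9, OCR = 0.2, D_material_cm2_s = 2e-5,
#'                  D_tissue_cm2_s = 2e-5, C_s = 0.2, C_crit_mol_m3 = 0,
#'                  couple_surface = FALSE)  # L ~ 2.22 mm
#' @export
design_thickness <- function(X, eta_target = 0.9, OCR = NULL,
                             D_material_cm2_s = NULL, D_tissue_cm2_s = NULL,
                             C_s = NULL, C_crit_mol_m3 = NULL,
                             couple_surface = is.null(C_s),
                             h_med_mm = 1.5, D_med_cm2_s = NULL,
                             C_amb = NULL, registry = o2_constants()) {
  stopifnot(X > 0, eta_target > 0, eta_target <= 1)
  if (is.null(OCR)) OCR <- registry$OCR_MIN6
  if (is.null(D_material_cm2_s)) D_material_cm2_s <- registry$D_water_37C
  if (is.null(D_tissue_cm2_s)) D_tissue_cm2_s <- registry$D_tissue
  if (is.null(C_crit_mol_m3))
    C_crit_mol_m3 <- convert_oxygen(o2(registry$pO2_crit, "mmHg"), "mol_m3",
                                    registry)$value
  if (is.null(D_med_cm2_s)) D_med_cm2_s <- registry$D_water_37C
  if (is.null(C_amb)) C_amb <- ambient_concentration(registry)$value
  # slab with a nominal thickness; x_v does not depend on it
  slab <- cellular_slab(1, X, OCR, D_material_cm2_s, D_tissue_cm2_s,
                        C_crit_mol_m3, registry)
  if (couple_surface) {
    sc <- .surface_fixed_point(slab, h_med_mm, D_med_cm2_s, C_amb,
                               cap_mm = Inf)
    C_s <- sc$C_s
    status <- sc$status
  } else {
    if (is.null(C_s)) stop("supply C_s or set couple_surface = TRUE",
                           call. = FALSE)
    status <- "ok"
  }
  if (C_s <= slab$C_crit)
    return(list(L_mm = NA_real_, x_v_mm = 0, C_s = C_s, phi = NA_real_,
                status = "oxygen_starved"))
  xv <- sqrt(2 * slab$D_eff_cm2_s * 1e-4 * (C_s - slab$C_crit) / slab$k_v) * 1e3
  L <- xv / eta_target
  phi <- thiele_modulus(L, X, OCR, slab$D_eff_cm2_s, C_s)
  list(L_mm = L, x_v_mm = xv, C_s = C_s, phi = phi, status = status)
}

#' Design curve: slab thickness versus cell concentration
#'
#' Maps [design_thickness()] over a grid of cell concentrations, converting
#' counts to volume fractions with [cells_to_fraction()].
#'
#' @param cells_per_mL vector of cell concentrations, cells mL^-1.
#' @param V_cell_pL single-cell volume, pL.
#' @param ... passed to [design_thickness()].
#' @param eta_target target effectiveness factor.
#' @return A data frame of class `design_curve` with columns
#'   `cells_per_mL`, `X`, `C_s`, `phi`, `eta`, `L_mm`; parameters echoed in
#'   attribute `"parameters"`.
#' @examples
#' dc <- design_curve(c(1e6, 5e6, 1e7), OCR = 0.034,
#'                    D_material_cm2_s = 2e-5, C_s = 0.15,
#'                    couple_surface = FALSE)
#' @export
design_curve <- function(cells_per_mL, V_cell_pL = 1.7, eta_target = 0.9,
                         ...) {
  X <- cells_to_fraction(cells_per_mL, V_cell_pL)
  rows <- lapply(X, function(x)
    design_thickness(x, eta_target = eta_target, ...))
  out <- data.frame(
    cells_per_mL = cells_per_mL,
    X = X,
    C_s = vapply(rows, `[[`, numeric(1), "C_s"),
    phi = vapply(rows, `[[`, numeric(1), "phi"),
    eta = eta_target,
    L_mm = vapply(rows, `[[`, numeric(1), "L_mm")
  )
  attr(out, "parameters") <- c(list(V_cell_pL = V_cell_pL,
                                    eta_target = eta_target), list(...))
  class(out) <- c("design_curve", "data.frame")
  out
}

#' @export
plot.design_curve <- function(x, ..., log = "xy",
                              xlab = "cell concentration (cells/mL)",
                              ylab = "slab thickness (mm)") {
  plot(x$cells_per_mL, x$L_mm, type = "b", log = log, xlab = xlab,
       ylab = ylab, ...)
  invisible(x)
}

#' Dimensionless transport report for one parameter set
#'
#' Bundles the Peclet number, Thiele modulus, critical Thiele modulus and
#' effectiveness factor for a single slab configuration.
#'
#' @param L_mm slab thickness, mm.
#' @param X cell volume fraction.
#' @param OCR volumetric consumption at X = 1, mol m^-3 s^-1.
#' @param D_material_cm2_s acellular gel diffusivity, cm^2 s^-1.
#' @param C_s surface concentration, mol m^-3.
#' @param C_crit_mol_m3 critical concentration, mol m^-3 (default 0).
#' @param u interface speed for Pe, m s^-1 (default 0: no advection).
#' @param D_tissue_cm2_s tissue diffusivity (registry default).
#' @param registry an [o2_constants()] registry.
#' @return A `dimensionless_report` list: `Pe`, `phi`, `phi_crit`, `eta`,
#'   and an `inputs` echo.
#' @export
dimensionless_report <- function(L_mm, X, OCR, D_material_cm2_s, C_s,
                                 C_crit_mol_m3 = 0, u = 0,
                                 D_tissue_cm2_s = NULL,
                                 registry = o2_constants()) {
  if (is.null(D_tissue_cm2_s)) D_tissue_cm2_s <- registry$D_tissue
  D_eff <- effective_diffusivity(X, D_tissue_cm2_s, D_material_cm2_s)
  c_ratio <- C_crit_mol_m3 / C_s
  phi <- thiele_modulus(L_mm, X, OCR, D_eff, C_s)
  structure(list(
    Pe = as.numeric(peclet(u, L_mm, D_eff)),
    phi = phi,
    phi_crit = sqrt(2 * (1 - c_ratio)),
    eta = effectiveness_factor(phi, c_ratio),
    inputs = list(u = u, L_mm = L_mm, X = X, OCR = OCR,
                  D_material_cm2_s = D_material_cm2_s,
                  D_eff_cm2_s = D_eff, C_s = C_s,
                  C_crit_mol_m3 = C_crit_mol_m3)
  ), class = "dimensionless_report")
}

#' @export
print.dimensionless_report <- function(x, ...) {
  cat("Dimensionless transport report:\n")
  cat(sprintf("  Pe       = %.3g (%s)\n", x$Pe,
              if (x$Pe < 1) "diffusion dominated" else "advection matters"))
  cat(sprintf("  phi      = %.3g (phi_crit = %.3g)\n", x$phi, x$phi_crit))
  cat(sprintf("  eta      = %.3g\n", x$eta))
  invisible(x)
}
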