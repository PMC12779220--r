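#' Cell-laden slab for steady-state reaction-diffusion
#'
#' A hydrogel slab of thickness `L` containing a cell volume fraction `X`.
#' Oxygen is consumed at the zero-order volumetric rate `k_v = X * OCR`
#' wherever the local concentration exceeds the critical level `C_crit`;
#' below it cells are dead and consume nothing. The effective diffusivity is
#' the cell-fraction-weighted average of the tissue and gel diffusivities
#' (see [effective_diffusivity()]).
#'
#' For this module depth `x` runs downward from the gel surface (x = 0 at
#' the top), the natural frame for penetration depths; the transient module
#' measures z upward from the dish bottom. `depth_to_height()` converts.
#'
#' @param L_mm slab thickness, mm.
#' @param X cell volume fraction in [0, 1).
#' @param OCR volumetric oxygen consumption rate at X = 1, mol m^-3 s^-1.
#' @param D_gel_cm2_s oxygen diffusivity of the acellular gel, cm^2 s^-1.
#' @param D_tissue_cm2_s oxygen diffusivity of tissue, cm^2 s^-1.
#' @param C_crit_mol_m3 critical oxygen concentration, mol m^-3; defaults to
#'   the concentration equivalent of `registry$pO2_crit` (0.1 mmHg).
#' @param registry an [o2_constants()] registry.
#' @return A `cellular_slab` object with derived fields `k_v` (mol m^-3 s^-1)
#'   and `D_eff_cm2_s`.
#' @export
cellular_slab <- function(L_mm, X, OCR = NULL, D_gel_cm2_s = NULL,
                          D_tissue_cm2_s = NULL, C_crit_mol_m3 = NULL,
                          registry = o2_constants()) {
  if (is.null(OCR)) OCR <- registry$OCR_MIN6
  if (is.null(D_gel_cm2_s)) D_gel_cm2_s <- registry$D_water_37C
  if (is.null(D_tissue_cm2_s)) D_tissue_cm2_s <- registry$D_tissue
  if (is.null(C_crit_mol_m3))
    C_crit_mol_m3 <- convert_oxygen(o2(registry$pO2_crit, "mmHg"), "mol_m3",
                                    registry)$value
  stopifnot(L_mm > 0, X >= 0, X < 1, OCR > 0, D_gel_cm2_s > 0,
            D_tissue_cm2_s > 0, C_crit_mol_m3 >= 0)
  structure(list(L_mm = L_mm, X = X, OCR = OCR,
                 D_gel_cm2_s = D_gel_cm2_s,
                 D_tissue_cm2_s = D_tissue_cm2_s,
                 C_crit = C_crit_mol_m3,
                 k_v = X * OCR,
                 D_eff_cm2_s = effective_diffusivity(X, D_tissue_cm2_s,
                                                     D_gel_cm2_s)),
            class = "cellular_slab")
}

#' @export
print.cellular_slab <- function(x, ...) {
  cat(sprintf(paste0("Cellular slab: L = %g mm, X = %.3g, k_v = %.3g",
                     " mol/m^3/s, D_eff = %.3g cm^2/s, C_crit = %.3g mol/m^3\n"),
              x$L_mm, x$X, x$k_v, x$D_eff_cm2_s, x$C_crit))
  invisible(x)
}

#' Convert slab depth (from the gel surface) to stack height (from the dish
#' bottom)
#'
#' @param depth_mm depth below the gel surface, mm.
#' @param L_mm slab thickness, mm.
#' @return Height above the slab bottom, mm.
#' @export
depth_to_height <- function(depth_mm, L_mm) L_mm - depth_mm

#' Oxygen penetration (viable-front) depth in a cell-laden slab
#'
#' Zero-order consumption below a surface held at `C_s` supports viable
#' cells down to `x_v = sqrt(2 D_eff (C_s - C_crit) / k_v)`; beyond the
#' front both the concentration excess and the flux vanish (smooth pasting).
#'
#' @param C_s surface oxygen concentration, mol m^-3.
#' @param slab a [cellular_slab()].
#' @return A list: `x_v_mm` (capped at `L` when the slab is fully viable),
#'   `fully_viable`, and `status` (`"ok"` or `"surface_below_critical"`,
#'   the latter returning depth 0 rather than an error).
#' @examples
#' s <- cellular_slab(3.5, 1e-3, OCR = 0.2, D_gel_cm2_s = 2e-5,
#'                    D_tissue_cm2_s = 2e-5, C_crit_mol_m3 = 0)
#' viable_depth(0.2, s)
#' @export
viable_depth <- function(C_s, slab) {
  stopifnot(inherits(slab, "cellular_slab"), C_s >= 0)
  if (slab$k_v == 0)
    return(list(x_v_mm = slab$L_mm, fully_viable = TRUE, status = "ok"))
  if (C_s <= slab$C_crit)
    return(list(x_v_mm = 0, fully_viable = FALSE,
                status = "surface_below_critical"))
  D <- slab$D_eff_cm2_s * 1e-4
  xv <- sqrt(2 * D * (C_s - slab$C_crit) / slab$k_v) * 1e3
  full <- xv >= slab$L_mm
  list(x_v_mm = if (full) slab$L_mm else xv, fully_viable = full,
       status = "ok")
}

#' Steady-state oxygen depth profile in a cell-laden slab
#'
#' Closed-form solution of the zero-order obstacle problem. In the viable
#' zone (x <= x_v): `C(x) = C_s - k_v/(2 D_eff) * x (2 x_v - x)`; past the
#' front the concentration sits at `C_crit` with zero flux. A fully viable
#' slab carries the parabola with zero flux at the slab bottom instead.
#'
#' @param C_s surface concentration, mol m^-3.
#' @param slab a [cellular_slab()].
#' @param n number of depth nodes (>= 2).
#' @return A `steady_profile`: `depth_mm`, `C_mol_m3`, `x_v_mm`, `eta`
#'   (viable fraction = effectiveness factor), `fully_viable`, `status`.
#' @export
steady_profile <- function(C_s, slab, n = 201) {
  stopifnot(inherits(slab, "cellular_slab"))
  if (n < 2) stop("at least 2 depth nodes required", call. = FALSE)
  vd <- viable_depth(C_s, slab)
  x <- seq(0, slab$L_mm, length.out = n)
  D <- slab$D_eff_cm2_s * 1e-4
  xm <- x * 1e-3
  if (slab$k_v == 0) {
    C <- rep(C_s, n)
  } else if (vd$status == "surface_below_critical") {
    C <- rep(C_s, n)  # no consumption anywhere: everything is dead
  } else if (vd$fully_viable) {
    L <- slab$L_mm * 1e-3
    C <- C_s - slab$k_v / (2 * D) * xm * (2 * L - xm)
  } else {
    xv <- vd$x_v_mm * 1e-3
    C <- ifelse(xm <= xv,
                C_s - slab$k_v / (2 * D) * xm * (2 * xv - xm),
                slab$C_crit)
  }
  eta <- min(1, vd$x_v_mm / slab$L_mm)
  structure(list(depth_mm = x, C_mol_m3 = pmax(C, 0),
                 x_v_mm = vd$x_v_mm, eta = eta,
                 fully_viable = vd$fully_viable, status = vd$status,
                 C_s = C_s, slab = slab),
            class = "steady_profile")
}

#' @export
print.steady_profile <- function(x, ...) {
  cat(sprintf("Steady profile: x_v = %.3g mm, eta = %.3g, %s\n",
              x$x_v_mm, x$eta,
              if (x$fully_viable) "fully viable" else "viable front inside slab"))
  invisible(x)
}

#' @export
plot.steady_profile <- function(x, ..., xlab = "depth from surface (mm)",
                                ylab = "oxygen (mol/m^3)") {
  plot(x$depth_mm, x$C_mol_m3, type = "l", xlab = xlab, ylab = ylab, ...)
  abline(v = x$x_v_mm, lty = 3)
  abline(h = x$slab$C_crit, lty = 3, col = "red3")
  invisible(x)
}

#' @export
as.data.frame.steady_profile <- function(x, ...) {
  data.frame(depth_mm = x$depth_mm, C_mol_m3 = x$C_mol_m3)
}

#' Brute-force finite-difference steady solver (oracle)
#'
#' Independent check on the closed-form profile: solves the discrete
#' masked-consumption problem -- zero-order consumption active only where
#' the concentration exceeds `C_crit`, concentration never below `C_crit`
#' -- as the equivalent complementarity (obstacle) system by projected SOR.
#'
#' @inheritParams steady_profile
#' @return A list: `depth_mm`, `C_mol_m3`, `x_v_mm` (first crossing of
#'   `C_crit`, linearly interpolated; `L` if none).
#' @export
steady_profile_fd <- function(C_s, slab, n = 401) {
  stopifnot(inherits(slab, "cellular_slab"), n >= 3)
  L <- slab$L_mm * 1e-3
  h <- L / (n - 1)
  D <- slab$D_eff_cm2_s * 1e-4
  x <- seq(0, L, length.out = n)
  C <- psor_obstacle(n, h, D, slab$k_v, slab$C_crit, C_s,
                     omega = 1.8, tol = 1e-12 * max(C_s, 1), maxit = 200000L)
  below <- which(C <= slab$C_crit + 1e-9 * max(C_s, 1))
  xv <- if (length(below) && slab$k_v > 0) {
    i <- below[1]
    if (i == 1) 0 else {
      x0 <- x[i - 1]; x1 <- x[i]
      x0 + (C[i - 1] - slab$C_crit) / (C[i - 1] - C[i] + 1e-300) * (x1 - x0)
    }
  } else L
  list(depth_mm = x * 1e3, C_mol_m3 = C, x_v_mm = min(xv, L) * 1e3)
}

# uncapped areal-consumption fixed point shared by surface_concentration()
# and the design pipeline; cap_mm = Inf removes the slab-thickness cap
.surface_fixed_point <- function(slab, h_med_mm, D_med_cm2_s, C_amb,
                                 cap_mm, tol = 1e-8) {
  R <- (h_med_mm * 1e-3) / (D_med_cm2_s * 1e-4)   # medium resistance, s/m
  areal <- function(Cs) {
    vd <- viable_depth(Cs, slab)
    xv <- if (is.finite(cap_mm)) min(vd$x_v_mm, cap_mm) else {
      # uncapped: recompute without the L cap
      if (slab$k_v == 0 || Cs <= slab$C_crit) 0 else
        sqrt(2 * slab$D_eff_cm2_s * 1e-4 * (Cs - slab$C_crit) / slab$k_v) * 1e3
    }
    slab$k_v * xv * 1e-3
  }
  f <- function(Cs) Cs - C_amb + areal(Cs) * R
  if (slab$k_v == 0 || f(C_amb) <= 0)
    return(list(C_s = C_amb, status = "ok"))
  lo <- slab$C_crit * (1 + 1e-12) + 1e-300
  root <- uniroot(f, c(lo, C_amb), tol = tol * C_amb)$root
  status <- if ((root - slab$C_crit) < 1e-9 * C_amb) "oxygen_starved" else "ok"
  list(C_s = root, status = status)
}

#' Surface oxygen concentration under a top-up medium layer
#'
#' The gel surface does not see the full ambient concentration: oxygen must
#' diffuse through the stagnant medium layer, and at steady state the flux
#' through the medium balances the areal consumption of the viable zone.
#' Solving the fixed point
#' `C_s = C_amb - k_v * min(x_v(C_s), L) * h_med / D_med`
#' couples the surface concentration to the cell fraction.
#'
#' @param slab a [cellular_slab()].
#' @param h_med_mm medium layer thickness, mm.
#' @param D_med_cm2_s medium diffusivity, cm^2 s^-1.
#' @param C_amb ambient concentration above the medium, mol m^-3 (see
#'   [ambient_concentration()]).
#' @return A list: `C_s` (in `(C_crit, C_amb]`) and `status` (`"ok"` or
#'   `"oxygen_starved"` when the balance pins the surface at the critical
#'   concentration).
#' @examples
#' s <- cellular_slab(3.5, 2e-3, OCR = 0.01, D_gel_cm2_s = 3.1e-5,
#'                    C_crit_mol_m3 = 0)
#' surface_concentration(s, 1.5, 3.1e-5, 0.19)
#' @export
surface_concentration <- function(slab, h_med_mm, D_med_cm2_s,
                                  C_amb = ambient_concentration()$value) {
  stopifnot(inherits(slab, "cellular_slab"), h_med_mm > 0, D_med_cm2_s > 0,
            C_amb > slab$C_crit)
  .surface_fixed_point(slab, h_med_mm, D_med_cm2_s, C_amb, cap_mm = slab$L_mm)
}

#' Predicted dimensionless viable length of a cell-laden slab
#'
#' Composes [surface_concentration()] (coupling through the top-up medium)
#' with [viable_depth()] and returns `min(1, x_v / L)` -- the ratio of the
#' depth of living cells to the slab depth, equal to the zero-order
#' effectiveness factor.
#'
#' @inheritParams surface_concentration
#' @param C_s optional fixed surface concentration; when supplied the medium
#'   coupling is skipped (`couple_surface` off).
#' @return A list: `viable_fraction`, `x_v_mm`, `C_s`, `status`.
#' @export
predict_viable_fraction <- function(slab, h_med_mm = 1.5,
                                    D_med_cm2_s = NULL,
                                    C_amb = ambient_concentration()$value,
                                    C_s = NULL) {
  stopifnot(inherits(slab, "cellular_slab"))
  if (is.null(D_med_cm2_s)) D_med_cm2_s <- o2_constants()$D_water_37C
  if (is.null(C_s)) {
    sc <- surface_concentration(slab, h_med_mm, D_med_cm2_s, C_amb)
    C_s <- sc$C_s
    status <- sc$status
  } else status <- "ok"
  vd <- viable_depth(C_s, slab)
  if (vd$status != "ok") status <- vd$status
  list(viable_fraction = min(1, vd$x_v_mm / slab$L_mm),
       x_v_mm = vd$x_v_mm, C_s = C_s, status = status)
}
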