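#' Solver settings for the transient march
#'
#' @param dz_mm node spacing target within each layer, mm (default 0.02,
#'   i.e. 20 um). Each layer gets `round(thickness/dz)` uniform cells so
#'   interfaces land exactly on grid nodes.
#' @param dt_s time-step of the Crank-Nicolson march, s (default 0.5).
#' @return A plain list of settings.
#' @export
solver_settings <- function(dz_mm = 0.02, dt_s = 0.5) {
  stopifnot(dz_mm > 0, dt_s > 0)
  list(dz_mm = dz_mm, dt_s = dt_s)
}

# node grid with interfaces on nodes; returns z (m) and per-edge D (m^2/s)
.build_grid <- function(stack, dz_mm) {
  z <- 0
  Dedge <- numeric(0)
  for (i in seq_along(stack$thickness_mm)) {
    th <- stack$thickness_mm[i]
    ncell <- max(2L, round(th / dz_mm))
    znew <- z[length(z)] + seq_len(ncell) * (th / ncell)
    z <- c(z, znew)
    Dedge <- c(Dedge, rep(stack$D_cm2_s[i] * 1e-4, ncell))  # cm^2/s -> m^2/s
  }
  list(z = z * 1e-3, Dedge = Dedge)  # mm -> m
}

#' Solve the 1D transient oxygen diffusion problem over a layer stack
#'
#' Marches Fick's second law, `dC/dt = d/dz(D dC/dz)` (optionally with a
#' zero-order volumetric sink masked below a critical concentration), over
#' the stack with a zero-flux glass bottom and the driver-imposed top
#' surface. Discretization: finite volumes on a per-layer uniform grid with
#' interfaces on nodes (so interfacial concentration and flux are continuous
#' by construction, partition coefficient 1), Crank-Nicolson time stepping.
#'
#' @param stack a [layer_stack()].
#' @param driver a [boundary_driver()]; the initial condition is uniform at
#'   `driver$C0`.
#' @param times strictly increasing output times, s.
#' @param settings a [solver_settings()] list.
#' @param top_bc `"dirichlet"` (driver-imposed surface, the measurement
#'   configuration) or `"sealed"` (zero flux at both ends, used for
#'   conservation checks).
#' @param reaction optional `list(k_v =, C_crit =)` zero-order sink
#'   (mol m^-3 s^-1; mol m^-3) applied wherever C exceeds `C_crit`.
#' @param init optional initial condition: a function of height (mm)
#'   returning mol m^-3, overriding the uniform `driver$C0` start.
#' @return A `transient_field`: grid `z_mm`, `times`, concentration matrix
#'   `C` (nodes x times, mol m^-3), and solver diagnostics.
#' @examples
#' stack <- geometry_preset("water")
#' drv <- boundary_driver("ideal_step", C0 = 0.2, C_final = 0)
#' fld <- solve_transient(stack, drv, times = seq(0, 600, by = 60),
#'                        settings = solver_settings(0.1, 2))
#' @export
solve_transient <- function(stack, driver, times,
                            settings = solver_settings(),
                            top_bc = c("dirichlet", "sealed"),
                            reaction = NULL, init = NULL) {
  stopifnot(inherits(stack, "layer_stack"), inherits(driver, "boundary_driver"))
  top_bc <- match.arg(top_bc)
  if (length(times) < 1 || any(times < 0) ||
      (length(times) > 1 && any(diff(times) <= 0)))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  g <- .build_grid(stack, settings$dz_mm)
  tmax <- max(times)
  nsteps <- if (tmax > 0) as.integer(ceiling(tmax / settings$dt_s)) else 0L
  tlev <- seq(0, by = settings$dt_s, length.out = nsteps + 1)
  bvals <- if (top_bc == "dirichlet") boundary_value(driver, tlev) else numeric(nsteps + 1)
  kv <- 0; ccrit <- 0
  if (!is.null(reaction)) {
    kv <- reaction$k_v
    ccrit <- if (is.null(reaction$C_crit)) 0 else reaction$C_crit
    stopifnot(kv >= 0, ccrit >= 0)
  }
  c_init <- if (is.null(init)) rep(driver$C0, length(g$z)) else {
    v <- init(g$z * 1e3)
    if (length(v) != length(g$z) || any(!is.finite(v)) || any(v < 0))
      stop("init must map heights to finite non-negative concentrations",
           call. = FALSE)
    v
  }
  C <- if (nsteps == 0) matrix(c_init, ncol = length(times),
                               nrow = length(g$z)) else
    cn_march(g$z, g$Dedge, c_init, bvals, settings$dt_s, nsteps,
             if (top_bc == "dirichlet") 0L else 1L, times, kv, ccrit)
  # round-off clamp: tiny negatives to zero, warn if beyond the floor
  scale <- max(driver$C0, driver$C_final, 1e-300)
  if (any(C < -1e-9 * scale))
    warning("negative concentrations beyond 1e-9*C0 clamped to zero")
  C[C < 0] <- 0
  structure(list(z_mm = g$z * 1e3, times = as.numeric(times), C = C,
                 stack = stack, driver = driver,
                 diagnostics = list(dz_mm = settings$dz_mm,
                                    dt_s = settings$dt_s,
                                    n_nodes = length(g$z),
                                    n_steps = nsteps, top_bc = top_bc,
                                    reaction = reaction)),
            class = "transient_field")
}

#' @export
print.transient_field <- function(x, ...) {
  cat(sprintf("Transient field: %d nodes x %d times (dz = %g mm, dt = %g s)\n",
              nrow(x$C), ncol(x$C), x$diagnostics$dz_mm, x$diagnostics$dt_s))
  invisible(x)
}

#' @export
plot.transient_field <- function(x, ..., xlab = "z (mm)",
                                 ylab = "oxygen (mol/m^3)") {
  matplot(x$z_mm, x$C, type = "l", lty = 1, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' @export
as.data.frame.transient_field <- function(x, ...) {
  data.frame(z_mm = rep(x$z_mm, times = ncol(x$C)),
             time_s = rep(x$times, each = nrow(x$C)),
             C_mol_m3 = as.vector(x$C))
}

#' Analytic single-layer step-response series
#'
#' Closed-form solution for a single slab of height H with uniform initial
#' concentration C0, an ideal step to 0 at the top surface and a zero-flux
#' bottom:
#' `C/C0 = sum_n [4(-1)^n / ((2n+1) pi)] cos((2n+1) pi z / (2H))
#'   exp(-(2n+1)^2 pi^2 D t / (4 H^2))`.
#' Used as the independent oracle for the numerical solver.
#'
#' @param D diffusivity, cm^2 s^-1.
#' @param H_mm slab height, mm.
#' @param z_mm height above the bottom, mm (vectorized).
#' @param t_s time, s (vectorized; `z_mm` and `t_s` recycle).
#' @param n_terms number of series terms (>= 1).
#' @return Normalized concentration C/C0 with attribute
#'   `"truncation_bound"`, the magnitude of the first omitted term.
#' @examples
#' analytic_single_layer(3.1e-5, 4, 1.8, 3600)  # ~0.173
#' @export
analytic_single_layer <- function(D, H_mm, z_mm, t_s, n_terms = 200) {
  if (n_terms < 1) stop("n_terms must be >= 1", call. = FALSE)
  stopifnot(all(z_mm >= 0), all(z_mm <= H_mm), all(t_s >= 0), D > 0)
  Dsi <- D * 1e-4
  H <- H_mm * 1e-3
  z <- z_mm * 1e-3
  k <- length(z) == 1 || length(t_s) == 1
  n <- 0:(n_terms - 1)
  lam <- (2 * n + 1) * pi / (2 * H)
  out <- 0
  for (i in seq_along(n)) {
    out <- out + (4 * (-1)^n[i] / ((2 * n[i] + 1) * pi)) *
      cos(lam[i] * z) * exp(-lam[i]^2 * Dsi * t_s)
  }
  bound <- (4 / ((2 * n_terms + 1) * pi)) *
    exp(-((2 * n_terms + 1) * pi / (2 * H))^2 * Dsi * min(t_s))
  structure(pmin(pmax(out, 0), 1), truncation_bound = bound)
}

#' Sample a transient field at the probe height
#'
#' Linear interpolation between the bracketing grid nodes at every stored
#' time.
#'
#' @param field a `transient_field` from [solve_transient()].
#' @param probe_height_mm height above the dish bottom, mm; defaults to the
#'   stack's probe height.
#' @return A [probe_trace()] in mol m^-3.
#' @export
sample_probe <- function(field, probe_height_mm = NULL) {
  stopifnot(inherits(field, "transient_field"))
  if (is.null(probe_height_mm)) probe_height_mm <- field$stack$probe_height_mm
  if (probe_height_mm < min(field$z_mm) || probe_height_mm > max(field$z_mm))
    stop("probe height outside the solution domain", call. = FALSE)
  vals <- apply(field$C, 2, function(col)
    approx(field$z_mm, col, xout = probe_height_mm)$y)
  probe_trace(field$times, vals, "mol_m3",
              metadata = list(probe_height_mm = probe_height_mm))
}
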