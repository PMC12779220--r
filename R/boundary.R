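#' Top-surface boundary driver
#'
#' The oxygen concentration imposed at the gas/liquid interface after the
#' inlet gas is switched. Three modes:
#' \describe{
#'   \item{constant}{stays at `C0` for all time.}
#'   \item{ideal_step}{jumps to `C_final` at t = 0.}
#'   \item{fopdt}{first-order-plus-dead-time: stays at `C0` until the dead
#'     time `theta`, then relaxes exponentially toward `C_final` with time
#'     constant `tau`. This is the empirically observed interface response to
#'     an inlet step (default theta = 3 s, tau = 23 s).}
#' }
#'
#' @param mode one of `"constant"`, `"ideal_step"`, `"fopdt"`.
#' @param C0 initial concentration, mol m^-3.
#' @param C_final asymptotic concentration, mol m^-3 (0 for an N2 purge).
#' @param theta dead time, s (fopdt).
#' @param tau time constant, s (fopdt).
#' @return A `boundary_driver` object.
#' @examples
#' drv <- boundary_driver("fopdt", C0 = 0.2, C_final = 0)
#' boundary_value(drv, c(0, 26, 120))
#' @export
boundary_driver <- function(mode = c("fopdt", "ideal_step", "constant"),
                            C0, C_final = 0, theta = 3, tau = 23) {
  mode <- match.arg(mode)
  if (C0 < 0 || C_final < 0)
    stop("concentrations must be non-negative", call. = FALSE)
  if (theta < 0) stop("dead time theta must be >= 0", call. = FALSE)
  if (mode == "fopdt" && tau <= 0)
    stop("time constant tau must be > 0", call. = FALSE)
  structure(list(mode = mode, C0 = C0, C_final = C_final,
                 theta = theta, tau = tau),
            class = "boundary_driver")
}

#' @export
print.boundary_driver <- function(x, ...) {
  cat(sprintf("Boundary driver: %s, C0 = %g, C_final = %g", x$mode, x$C0,
              x$C_final))
  if (x$mode == "fopdt")
    cat(sprintf(", theta = %g s, tau = %g s", x$theta, x$tau))
  cat("\n")
  invisible(x)
}

#' Evaluate a boundary driver
#'
#' @param driver a [boundary_driver()].
#' @param t times, s (vectorized, must be >= 0).
#' @return Concentration(s) at the top surface, mol m^-3.
#' @export
boundary_value <- function(driver, t) {
  stopifnot(inherits(driver, "boundary_driver"))
  if (any(t < 0)) stop("negative times are not allowed", call. = FALSE)
  switch(driver$mode,
    constant = rep(driver$C0, length(t)),
    ideal_step = rep(driver$C_final, length(t)),
    fopdt = ifelse(t < driver$theta, driver$C0,
                   driver$C_final + (driver$C0 - driver$C_final) *
                     exp(-(t - driver$theta) / driver$tau))
  )
}

#' Time for the boundary to approach its final value
#'
#' Finds, by root bracketing on [boundary_value()], the time at which the
#' remaining departure from `C_final` falls to `fraction` of the initial
#' departure. For an fopdt driver this is theta + tau*log(1/fraction).
#'
#' @param driver a [boundary_driver()] with `C0 != C_final`.
#' @param fraction remaining departure, in (0, 1) (default 0.01).
#' @return Time in seconds.
#' @examples
#' equilibration_time(boundary_driver("fopdt", C0 = 1))  # ~109 s
#' @export
equilibration_time <- function(driver, fraction = 0.01) {
  stopifnot(inherits(driver, "boundary_driver"), fraction > 0, fraction < 1)
  if (driver$mode == "ideal_step") return(0)
  if (driver$mode == "constant")
    stop("a constant driver never departs from its initial value", call. = FALSE)
  dep0 <- abs(driver$C0 - driver$C_final)
  if (dep0 == 0) return(0)
  f <- function(t) abs(boundary_value(driver, t) - driver$C_final) / dep0 -
    fraction
  upper <- driver$theta + driver$tau * (log(1 / fraction) + 5)
  uniroot(f, c(driver$theta, upper), tol = 1e-10)$root
}
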