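#' Mean absolute percent error between a model and an observed trace
#'
#' `MAPE = (100/N) * sum_i |m_i - o_i| / max(o_i, eps*C0)` over the fit
#' window, where `C0` is the first observed value. The denominator floor
#' `eps*C0` keeps the objective finite as readings approach zero during an
#' N2 purge.
#'
#' @param model,observed [probe_trace()]s on identical time grids and in the
#'   same unit.
#' @param eps denominator floor as a fraction of the observed initial value
#'   (default 0.02).
#' @param window time interval `c(t0, t1)` to score (default: whole trace).
#' @return MAPE in percent (>= 0; 0 iff the traces agree on the window).
#' @examples
#' a <- probe_trace(0:2, c(1, 0.5, 0.25))
#' b <- probe_trace(0:2, c(1, 0.6, 0.25))
#' mape(b, a)  # 6.67
#' @export
mape <- function(model, observed, eps = 0.02, window = NULL) {
  stopifnot(inherits(model, "probe_trace"), inherits(observed, "probe_trace"))
  if (length(model$times) != length(observed$times) ||
      any(model$times != observed$times))
    stop("model and observed traces must share one time grid", call. = FALSE)
  if (model$unit != observed$unit)
    stop("model and observed traces must share one unit", call. = FALSE)
  stopifnot(eps > 0)
  keep <- rep(TRUE, length(observed$times))
  if (!is.null(window))
    keep <- observed$times >= window[1] & observed$times <= window[2]
  if (!any(keep)) stop("empty fit window", call. = FALSE)
  C0 <- observed$values[1]
  denom <- pmax(observed$values[keep], eps * C0)
  100 * mean(abs(model$values[keep] - observed$values[keep]) / denom)
}

#' Fit configuration for diffusion-coefficient estimation
#'
#' @param target_layer index of the layer whose diffusivity is estimated
#'   (default 1, the bottom layer).
#' @param D_bounds search interval for D, cm^2 s^-1 (default 1e-6 to 1e-4).
#' @param rel_tol relative convergence tolerance on D (default 1e-3).
#' @param window fit window `c(t0, t1)` in s, or `NULL` to use the default
#'   window: from the step onset until the observed trace first drops below
#'   1% of its initial value (or the trace end).
#' @param eps MAPE denominator floor as a fraction of C0 (default 0.02).
#' @return A `fit_config` list.
#' @export
fit_config <- function(target_layer = 1L, D_bounds = c(1e-6, 1e-4),
                       rel_tol = 1e-3, window = NULL, eps = 0.02) {
  stopifnot(length(D_bounds) == 2, D_bounds[1] > 0,
            D_bounds[2] > D_bounds[1], rel_tol > 0, rel_tol < 1, eps > 0)
  structure(list(target_layer = as.integer(target_layer),
                 D_bounds = D_bounds, rel_tol = rel_tol,
                 window = window, eps = eps), class = "fit_config")
}

.default_window <- function(observed) {
  C0 <- observed$values[1]
  below <- which(observed$values < 0.01 * C0)
  t1 <- if (length(below)) observed$times[below[1]] else
    observed$times[length(observed$times)]
  c(observed$times[1], t1)
}

#' Estimate a layer's oxygen diffusion coefficient from a probe trace
#'
#' The central estimator of the package: bounded one-dimensional
#' minimization (Brent's golden-section/parabolic method on log10 D) of the
#' mean absolute percent error between the observed probe trace and the
#' transient model evaluated at the observation times. The trace is
#' converted to mol m^-3 internally, so the estimate is invariant to the
#' recording unit.
#'
#' @param observed a [probe_trace()] (any supported unit).
#' @param stack a [layer_stack()] template; the target layer's diffusivity
#'   entry is ignored and estimated. When fitting a gel layer the medium
#'   layer's diffusivity is held at its template value (conventionally the
#'   diffusivity of water at 37 C).
#' @param driver a [boundary_driver()] describing the applied gas step.
#' @param config a [fit_config()].
#' @param settings [solver_settings()] used for every model evaluation.
#' @param registry an [o2_constants()] registry (unit conversions).
#' @return An object of class `diffusion_fit` with components `D_hat`
#'   (cm^2 s^-1), `objective` (MAPE, %), `iterations`, `converged` (FALSE if
#'   the minimizer sits on a search bound), `residuals`, the fitted model
#'   trace, the fit window and all inputs. Methods: `print`, `summary`,
#'   `coef`, `predict`, `fitted`, `residuals`, `plot`, `simulate`.
#' @examples
#' \donttest{
#' spec <- make_fixture("water_37C")
#' obs <- generate_trace(spec)
#' fit <- fit_diffusion(obs, spec$stack, spec$driver,
#'                      settings = solver_settings(0.05, 2))
#' coef(fit)
#' }
#' @export
fit_diffusion <- function(observed, stack, driver, config = fit_config(),
                          settings = solver_settings(),
                          registry = o2_constants()) {
  stopifnot(inherits(observed, "probe_trace"), inherits(stack, "layer_stack"),
            inherits(driver, "boundary_driver"), inherits(config, "fit_config"))
  obs <- convert_trace(observed, "mol_m3", registry)
  window <- if (is.null(config$window)) .default_window(obs) else config$window
  if (obs$times[1] > window[1] ||
      obs$times[length(obs$times)] < window[2])
    stop("observed trace does not cover the fit window", call. = FALSE)
  if (config$target_layer < 1 || config$target_layer > length(stack$D_cm2_s))
    stop("target_layer outside the stack", call. = FALSE)

  neval <- 0L
  model_at <- function(D) {
    st <- stack
    st$D_cm2_s[config$target_layer] <- D
    fld <- solve_transient(st, driver, obs$times, settings = settings)
    sample_probe(fld)
  }
  obj <- function(l10D) {
    neval <<- neval + 1L
    mape(model_at(10^l10D), obs, eps = config$eps, window = window)
  }
  lb <- log10(config$D_bounds[1]); ub <- log10(config$D_bounds[2])
  opt <- optimize(obj, c(lb, ub), tol = config$rel_tol / log(10))
  D_hat <- 10^opt$minimum
  at_bound <- (opt$minimum - lb) < 2 * config$rel_tol ||
    (ub - opt$minimum) < 2 * config$rel_tol
  model <- model_at(D_hat)
  structure(list(D_hat = D_hat, objective = opt$objective,
                 iterations = neval, converged = !at_bound,
                 residuals = model$values - obs$values,
                 model = model, observed = obs, window = window,
                 stack = stack, driver = driver, config = config,
                 settings = settings, call = match.call()),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat("Oxygen diffusion coefficient fit (MAPE minimization)\n")
  cat(sprintf("  D_hat     = %.4g cm^2/s\n", x$D_hat))
  cat(sprintf("  MAPE      = %.3g %%  (%d model evaluations)\n",
              x$objective, x$iterations))
  cat(sprintf("  window    = [%g, %g] s\n", x$window[1], x$window[2]))
  if (!x$converged)
    cat("  WARNING: minimizer at a search bound; estimate unreliable\n")
  invisible(x)
}

#' @export
summary.diffusion_fit <- function(object, ...) {
  r <- object$residuals
  out <- list(D_hat = object$D_hat, objective = object$objective,
              converged = object$converged, iterations = object$iterations,
              window = object$window,
              residual_sd = sd(r), residual_range = range(r),
              n = length(r))
  class(out) <- "summary.diffusion_fit"
  out
}

#' @export
print.summary.diffusion_fit <- function(x, ...) {
  cat(sprintf("D_hat = %.4g cm^2/s, MAPE = %.3g%%, n = %d, converged: %s\n",
              x$D_hat, x$objective, x$n, x$converged))
  cat(sprintf("residual sd = %.3g mol/m^3, range [%.3g, %.3g]\n",
              x$residual_sd, x$residual_range[1], x$residual_range[2]))
  invisible(x)
}

#' @export
coef.diffusion_fit <- function(object, ...) {
  c(D_cm2_s = object$D_hat)
}

#' @export
fitted.diffusion_fit <- function(object, ...) object$model$values

#' @export
residuals.diffusion_fit <- function(object, ...) object$residuals

#' Predict the model trace at new times from a fitted diffusion coefficient
#'
#' @param object a `diffusion_fit`.
#' @param times output times, s (default: the observation times).
#' @param ... unused.
#' @return A [probe_trace()] in mol m^-3.
#' @export
predict.diffusion_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$model)
  st <- object$stack
  st$D_cm2_s[object$config$target_layer] <- object$D_hat
  fld <- solve_transient(st, object$driver, times, settings = object$settings)
  sample_probe(fld)
}

#' @export
plot.diffusion_fit <- function(x, ..., xlab = "time (s)",
                               ylab = "oxygen (mol/m^3)") {
  plot(x$observed$times, x$observed$values, pch = 16, cex = 0.4,
       xlab = xlab, ylab = ylab, col = "grey40", ...)
  lines(x$model$times, x$model$values, col = "red3", lwd = 2)
  abline(v = x$window, lty = 3)
  legend("topright", c("observed", "model"), pch = c(16, NA),
         lty = c(NA, 1), col = c("grey40", "red3"), bty = "n")
  invisible(x)
}

#' Simulate noisy traces from a fitted model
#'
#' Adds independent Gaussian noise at the residual standard deviation to the
#' fitted trace, one [probe_trace()] per replicate.
#'
#' @param object a `diffusion_fit`.
#' @param nsim number of replicates.
#' @param seed RNG seed (restored afterwards).
#' @param ... unused.
#' @return A list of `probe_trace`s.
#' @export
simulate.diffusion_fit <- function(object, nsim = 1, seed = NULL, ...) {
  s <- sd(object$residuals)
  with_seed(seed, lapply(seq_len(nsim), function(i)
    probe_trace(object$model$times,
                object$model$values + rnorm(length(object$model$values), 0, s),
                "mol_m3")))
}

#' Summarize replicate diffusion-coefficient fits
#'
#' @param results a list of `diffusion_fit` objects, or a numeric vector of
#'   fitted coefficients.
#' @return A list with `mean`, `sd` (n-1 denominator), `sem` (`sd/sqrt(n)`)
#'   and `n`, all in cm^2 s^-1.
#' @examples
#' aggregate_replicates(c(3.0e-5, 3.2e-5, 3.4e-5))
#' @export
aggregate_replicates <- function(results) {
  if (is.list(results))
    results <- vapply(results, function(r) {
      stopifnot(inherits(r, "diffusion_fit")); r$D_hat
    }, numeric(1))
  if (!length(results)) stop("no replicates supplied", call. = FALSE)
  n <- length(results)
  s <- if (n > 1) sd(results) else 0
  list(mean = mean(results), sd = s, sem = s / sqrt(n), n = n)
}

# evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
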