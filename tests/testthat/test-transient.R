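test_that("a constant driver leaves the field at equilibrium", {
  stack <- geometry_preset("water")
  fld <- solve_transient(stack, boundary_driver("constant", C0 = 0.2),
                         times = c(0, 600, 1800), settings = quick_settings)
  expect_true(all(abs(fld$C - 0.2) < 1e-12))
})

test_that("numerical solver matches the cosine-series oracle on the step problem", {
  D <- 3.1e-5; H <- 4; z <- 1.8
  stack <- layer_stack(H, D, probe_height_mm = z)
  drv <- boundary_driver("ideal_step", C0 = 1, C_final = 0)
  # Fourier numbers from ~0.01 upward
  times <- c(60, 120, 300, 600, 1200, 1800, 2400, 3600)
  fld <- solve_transient(stack, drv, times)   # default resolution
  tr <- sample_probe(fld)
  exact <- analytic_single_layer(D, H, z, times)
  expect_true(all(abs(tr$values - exact) < 0.005))
  # the spot value at one hour
  expect_equal(tr$values[times == 3600], 0.173, tolerance = 0.005 / 0.173)
})

test_that("analytic series satisfies its boundary and initial conditions", {
  expect_equal(as.numeric(analytic_single_layer(3.1e-5, 4, 1.3, 0,
                                                n_terms = 400)),
               1, tolerance = 0.005)
  expect_equal(as.numeric(analytic_single_layer(3.1e-5, 4, 4, 1000)), 0)
  expect_error(analytic_single_layer(3.1e-5, 4, 1, 10, n_terms = 0), "n_terms")
  # truncation bound is reported and small for moderate times
  b <- attr(analytic_single_layer(3.1e-5, 4, 1.8, 3600), "truncation_bound")
  expect_lt(b, 1e-10)
})

test_that("two layers with equal diffusivity reduce to one layer", {
  drv <- boundary_driver("ideal_step", C0 = 1, C_final = 0)
  times <- seq(0, 3600, by = 360)
  one <- sample_probe(solve_transient(layer_stack(4, 3.1e-5), drv, times,
                                      settings = quick_settings))
  two <- sample_probe(solve_transient(
    layer_stack(c(2.5, 1.5), c(3.1e-5, 3.1e-5)), drv, times,
    settings = quick_settings))
  expect_true(all(abs(one$values - two$values) < 1e-6))
})

test_that("probe trace after a step down is monotone, bounded, and vanishing", {
  stack <- geometry_preset("water")
  drv <- boundary_driver("ideal_step", C0 = 0.2, C_final = 0)
  tr <- sample_probe(solve_transient(stack, drv, seq(0, 30000, by = 300),
                                     settings = quick_settings))
  expect_true(all(diff(tr$values) <= 1e-6 * 0.2))
  expect_true(all(tr$values <= 0.2 + 1e-6 * 0.2))
  expect_true(all(tr$values >= -1e-6 * 0.2))
  expect_lt(tr$values[length(tr$values)], 1e-3 * 0.2)  # t -> infinity limit
})

test_that("sealed slab conserves mass from a nonuniform start", {
  stack <- layer_stack(4, 3.1e-5)
  drv <- boundary_driver("constant", C0 = 1)
  init <- function(z_mm) 0.5 + 0.5 * cos(pi * z_mm / 4)
  times <- seq(0, 500, by = 50)   # 1000 steps at dt = 0.5
  fld <- solve_transient(stack, drv, times, top_bc = "sealed", init = init)
  # trapezoidal mass on the (uniform within layer) grid
  mass <- apply(fld$C, 2, function(col) {
    h <- diff(fld$z_mm)
    sum((col[-1] + col[-length(col)]) / 2 * h)
  })
  expect_true(all(abs(mass - mass[1]) / mass[1] < 1e-10))
})

test_that("halving grid and step changes the probe solution by < 0.2% of C0", {
  stack <- geometry_preset("water")
  drv <- boundary_driver("ideal_step", C0 = 1, C_final = 0)
  times <- seq(300, 3600, by = 300)
  coarse <- sample_probe(solve_transient(stack, drv, times,
                                         solver_settings(0.02, 0.5)))
  fine <- sample_probe(solve_transient(stack, drv, times,
                                       solver_settings(0.01, 0.25)))
  expect_true(all(abs(coarse$values - fine$values) < 0.002))
})

test_that("probe sampling interpolates linearly and validates its domain", {
  stack <- layer_stack(4, 3.1e-5)
  drv <- boundary_driver("ideal_step", C0 = 1, C_final = 0)
  fld <- solve_transient(stack, drv, c(0, 600), settings = quick_settings)
  # on a node: equals the node value
  iz <- 11
  on_node <- sample_probe(fld, fld$z_mm[iz])
  expect_equal(on_node$values, fld$C[iz, ])
  # midway between nodes: the average
  mid <- sample_probe(fld, mean(fld$z_mm[iz:(iz + 1)]))
  expect_equal(mid$values, colMeans(fld$C[iz:(iz + 1), ]))
  expect_error(sample_probe(fld, 5), "outside")
})

test_that("invalid geometry, times, and drivers are rejected", {
  expect_error(layer_stack(c(3.5, 0), c(1e-5, 1e-5)), "> 0")
  expect_error(layer_stack(4, -1e-5), "> 0")
  expect_error(layer_stack(4, 1e-5, probe_height_mm = 9), "probe")
  expect_error(layer_stack(c(1, 1, 1), rep(1e-5, 3)), "2 layers")
  stack <- layer_stack(4, 3.1e-5)
  drv <- boundary_driver("ideal_step", C0 = 1, C_final = 0)
  expect_error(solve_transient(stack, drv, c(10, 5)), "increasing")
  expect_error(solve_transient(stack, drv, c(-5, 10)), "increasing|negative")
})
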