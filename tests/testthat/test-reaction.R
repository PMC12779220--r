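test_that("viable depth follows the zero-order closed form", {
  s <- plain_slab(L_mm = 3.5, k_v = 2e-4, D = 2e-5, C_crit = 0)
  vd <- viable_depth(0.2, s)
  expect_equal(vd$x_v_mm, 2.0, tolerance = 1e-12)   # sqrt(4e-6) m
  expect_false(vd$fully_viable)
  # no consumption: trivially fully viable
  s0 <- cellular_slab(3.5, 0, OCR = 0.129, D_gel_cm2_s = 2e-5)
  expect_true(viable_depth(0.1, s0)$fully_viable)
  expect_equal(viable_depth(0.1, s0)$x_v_mm, 3.5)
  # surface at/below critical: depth zero with a distinct status, no error
  s2 <- plain_slab(C_crit = 0.05)
  vd2 <- viable_depth(0.04, s2)
  expect_equal(vd2$x_v_mm, 0)
  expect_equal(vd2$status, "surface_below_critical")
})

test_that("the steady profile satisfies the smooth-pasting front conditions", {
  s <- plain_slab(L_mm = 3.5, k_v = 2e-4, D = 2e-5, C_crit = 0)
  pr <- steady_profile(0.2, s, n = 2001)
  expect_equal(pr$x_v_mm, 2.0, tolerance = 1e-9)
  expect_equal(pr$eta, 2.0 / 3.5, tolerance = 1e-9)
  # C(x_v) = C_crit and zero slope at the front
  i <- which.min(abs(pr$depth_mm - pr$x_v_mm))
  expect_lt(pr$C_mol_m3[i], 1e-6 * 0.2)
  slope <- diff(pr$C_mol_m3[(i - 1):i]) / diff(pr$depth_mm[(i - 1):i])
  expect_lt(abs(slope), 1e-3 * 0.2)   # mol/m^3 per mm, vanishing at the front
  # non-increasing, non-negative
  expect_true(all(diff(pr$C_mol_m3) <= 1e-12))
  expect_true(all(pr$C_mol_m3 >= 0))
  # no consumption: uniform at the surface value
  s0 <- cellular_slab(3.5, 0, OCR = 0.129, D_gel_cm2_s = 2e-5)
  expect_true(all(steady_profile(0.2, s0)$C_mol_m3 == 0.2))
})

test_that("closed form and masked finite-difference oracle agree across a sweep", {
  n <- 401
  for (D in c(1e-5, 2e-5, 3e-5))
    for (k_v in c(5e-5, 2e-4, 8e-4))
      for (C_s in c(0.1, 0.16, 0.22)) {
        s <- plain_slab(L_mm = 3.5, k_v = k_v, D = D, C_crit = 1.2e-4)
        vd <- viable_depth(C_s, s)
        fd <- steady_profile_fd(C_s, s, n = n)
        h <- 3.5 / (n - 1)
        expect_lt(abs(vd$x_v_mm - fd$x_v_mm), h + 1e-9)
        # concentration agreement within 1% of the surface value
        pr <- steady_profile(C_s, s, n = n)
        expect_lt(max(abs(pr$C_mol_m3 - fd$C_mol_m3)), 0.01 * C_s)
      }
})

test_that("viable fraction equals the zero-order effectiveness factor", {
  s <- plain_slab(L_mm = 3.5, k_v = 2e-4, D = 2e-5, C_crit = 1.2e-4)
  for (C_s in c(0.05, 0.1, 0.2)) {
    vd <- viable_depth(C_s, s)
    phi <- thiele_modulus(s$L_mm, s$X, s$OCR, s$D_eff_cm2_s, C_s)
    eta <- effectiveness_factor(phi, s$C_crit / C_s)
    expect_equal(min(1, vd$x_v_mm / s$L_mm), eta, tolerance = 1e-12)
  }
})

test_that("effectiveness approaches 1 continuously at the fully-viable boundary", {
  s <- plain_slab(L_mm = 2.0, k_v = 2e-4, D = 2e-5, C_crit = 0)
  # x_v = L exactly when C_s = k_v L^2 / (2 D_eff)
  C_star <- s$k_v * (2e-3)^2 / (2 * s$D_eff_cm2_s * 1e-4)
  eta <- vapply(C_star * c(0.99, 0.999, 1, 1.001, 1.01), function(C_s)
    min(1, viable_depth(C_s, s)$x_v_mm / s$L_mm), numeric(1))
  expect_true(all(diff(eta) >= 0))
  expect_equal(eta[3], 1, tolerance = 1e-9)
  expect_gt(eta[1], 0.99)
})

test_that("surface concentration balances medium flux against consumption", {
  # fully viable slab: one-step closed form
  s <- cellular_slab(3.5, 2e-3, OCR = 0.01, D_gel_cm2_s = 3.1e-5,
                     C_crit_mol_m3 = 0)   # k_v = 2e-5
  sc <- surface_concentration(s, 1.5, 3.1e-5, C_amb = 0.19)
  expect_equal(sc$C_s, 0.19 - 2e-5 * 3.5e-3 * 1.5e-3 / 3.1e-9,
               tolerance = 1e-6)
  expect_equal(sc$status, "ok")
  # self-consistency of the fixed point
  vd <- viable_depth(sc$C_s, s)
  flux_drop <- s$k_v * min(vd$x_v_mm, s$L_mm) * 1e-3 * 1.5e-3 / 3.1e-9
  expect_equal(sc$C_s + flux_drop, 0.19, tolerance = 1e-6)
  # no cells: surface sees the full ambient concentration
  s0 <- cellular_slab(3.5, 0, OCR = 0.129, D_gel_cm2_s = 3.1e-5)
  expect_equal(surface_concentration(s0, 1.5, 3.1e-5, 0.19)$C_s, 0.19)
})

test_that("surface concentration decreases strictly with cell fraction", {
  Cs <- vapply(c(1e-4, 1e-3, 3e-3, 1e-2, 3e-2), function(X) {
    s <- cellular_slab(3.5, X, OCR = 0.129, D_gel_cm2_s = 2.4e-5,
                       C_crit_mol_m3 = 1.2e-4)
    surface_concentration(s, 1.5, 3.1e-5, 0.159)$C_s
  }, numeric(1))
  expect_true(all(diff(Cs) < 0))
})

test_that("predicted viable fraction reproduces the tabulated front regime", {
  # parameters tuned so phi = 2.31 with negligible C_crit
  D <- 2e-5; C_s <- 0.15; L <- 3.5
  k_v <- 2.31^2 * (D * 1e-4) * C_s / (L * 1e-3)^2
  s <- plain_slab(L_mm = L, k_v = k_v, D = D, C_crit = 0)
  pv <- predict_viable_fraction(s, C_s = C_s)
  expect_equal(thiele_modulus(L, s$X, s$OCR, s$D_eff_cm2_s, C_s), 2.31,
               tolerance = 1e-12)
  expect_equal(trunc_decimals(pv$viable_fraction, 2), 0.61)
  # no cells: fully viable
  s0 <- cellular_slab(3.5, 0, OCR = 0.129, D_gel_cm2_s = 2e-5)
  expect_equal(predict_viable_fraction(s0, C_s = 0.1)$viable_fraction, 1)
})

test_that("viable fraction never increases with cell fraction", {
  vf <- vapply(c(1e-3, 3e-3, 1e-2, 3e-2, 1e-1), function(X) {
    s <- cellular_slab(3.5, X, OCR = 0.129, D_gel_cm2_s = 2.4e-5,
                       C_crit_mol_m3 = 1.2e-4)
    predict_viable_fraction(s)$viable_fraction
  }, numeric(1))
  expect_true(all(diff(vf) <= 0))
})

test_that("transient solver with a masked sink relaxes to the steady profile", {
  # single gel slab held at C_s on top; depth x (steady frame) = L - z
  D <- 2e-5; k_v <- 2e-4; C_s <- 0.2; C_crit <- 1.2e-4
  s <- plain_slab(L_mm = 3.5, k_v = k_v, D = D, C_crit = C_crit)
  stack <- layer_stack(3.5, D)
  drv <- boundary_driver("constant", C0 = C_s)
  fld <- solve_transient(stack, drv, times = c(0, 30000),
                         settings = solver_settings(0.05, 1),
                         reaction = list(k_v = k_v, C_crit = C_crit))
  Cend <- fld$C[, 2]
  pr <- steady_profile(C_s, s, n = length(Cend))
  # flip the steady profile into the height frame before comparing
  expect_lt(max(abs(Cend - rev(pr$C_mol_m3))), 0.01 * C_s)
})

test_that("depth and height frames convert consistently", {
  expect_equal(depth_to_height(0, 3.5), 3.5)
  expect_equal(depth_to_height(3.5, 3.5), 0)
  expect_equal(depth_to_height(depth_to_height(1.2, 3.5), 3.5), 1.2)
})
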