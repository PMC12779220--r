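test_that("Peclet number flags diffusion dominance", {
  expect_equal(as.numeric(peclet(0, 4, 3.1e-5)), 0)
  expect_true(attr(peclet(0, 4, 3.1e-5), "diffusion_dominated"))
  # definitional balance point u = D/L
  pe1 <- peclet(3.1e-9 / 4e-3, 4, 3.1e-5)
  expect_equal(as.numeric(pe1), 1, tolerance = 1e-12)
  expect_false(attr(peclet(2 * 3.1e-9 / 4e-3, 4, 3.1e-5),
                    "diffusion_dominated"))
  expect_equal(as.numeric(peclet(1e-6, 4, 3.1e-5)), 1e-6 * 4e-3 / 3.1e-9,
               tolerance = 1e-12)
  expect_error(peclet(-1e-6, 4, 3.1e-5), "speed")
})

test_that("cell concentration converts to volume fraction and rejects overpacking", {
  expect_equal(cells_to_fraction(0), 0)
  expect_equal(cells_to_fraction(1.2e6, 1.7), 2.04e-3, tolerance = 1e-12)
  expect_equal(cells_to_fraction(1e7, 1.7), 1.7e-2, tolerance = 1e-12)
  expect_error(cells_to_fraction(1e12, 1.7), "unphysical")
})

test_that("effective diffusivity interpolates between material and tissue", {
  expect_equal(effective_diffusivity(0, 1.24e-5, 3.1e-5), 3.1e-5)
  expect_equal(effective_diffusivity(1, 1.24e-5, 3.1e-5), 1.24e-5)
  expect_equal(effective_diffusivity(0.5, 1.24e-5, 3.1e-5), 2.17e-5)
  expect_error(effective_diffusivity(1.5, 1.24e-5, 3.1e-5), "0, 1")
})

test_that("Thiele modulus follows its defining arithmetic and scaling", {
  # L = 1 mm, k_v = 4e-4, D_eff = 1e-5 cm^2/s, C_s = 0.1 -> phi = 2
  expect_equal(thiele_modulus(1, 1, 4e-4, 1e-5, 0.1), 2, tolerance = 1e-12)
  phi1 <- thiele_modulus(3.5, 0.01, 0.129, 2.4e-5, 0.15)
  phi2 <- thiele_modulus(3.5, 0.02, 0.129, 2.4e-5, 0.15)
  expect_equal(phi2 / phi1, sqrt(2), tolerance = 1e-12)
  expect_equal(thiele_modulus(1, 0, 0.1, 1e-5, 0.1), 0)
  expect_error(thiele_modulus(1, 1, 0.1, 1e-5, 0), "C_s")
})

test_that("cell-density ratio of Thiele moduli matches the tabulated pairs", {
  computed <- sqrt(10 / 1.2)
  for (r in c(6.67 / 2.31, 5.14 / 1.78, 7.79 / 2.69))
    expect_lt(abs(computed - r) / r, 0.005)
})

test_that("effectiveness factor is the standard zero-order slab form", {
  expect_equal(effectiveness_factor(1.0), 1)
  expect_equal(effectiveness_factor(sqrt(2)), 1)           # at phi_crit
  expect_equal(effectiveness_factor(2.31), sqrt(2) / 2.31, tolerance = 1e-12)
  expect_equal(trunc_decimals(effectiveness_factor(2.31), 2), 0.61)
  expect_equal(trunc_decimals(effectiveness_factor(7.79), 2), 0.18)
  # eta * phi = sqrt(2 (1 - c)) beyond phi_crit; eta = 1 below
  for (cr in c(0, 0.2, 0.6)) {
    phis <- seq(0.01, 10, length.out = 200)
    eta <- effectiveness_factor(phis, cr)
    crit <- sqrt(2 * (1 - cr))
    expect_true(all(eta[phis <= crit] == 1))
    above <- phis > crit
    expect_equal(eta[above] * phis[above], rep(crit, sum(above)),
                 tolerance = 1e-12)
  }
  expect_error(effectiveness_factor(2, c_ratio = 1), "c_ratio")
  expect_error(effectiveness_factor(-1), "phi")
})

test_that("truncation (not rounding) reproduces tabulated two-decimal values", {
  expect_equal(trunc_decimals(0.5257, 2), 0.52)   # rounding would give 0.53
  expect_equal(trunc_decimals(0.2751, 2), 0.27)
  expect_equal(trunc_decimals(0.61, 2), 0.61)
})

test_that("design thickness inverts the viable depth at the target effectiveness", {
  d <- design_thickness(1e-3, 0.9, OCR = 0.2, D_material_cm2_s = 2e-5,
                        D_tissue_cm2_s = 2e-5, C_s = 0.2,
                        C_crit_mol_m3 = 0, couple_surface = FALSE)
  expect_equal(d$x_v_mm, 2.0, tolerance = 1e-12)
  expect_equal(d$L_mm, 2.0 / 0.9, tolerance = 1e-12)
  # eta_target = 1 sizes the slab at exactly the viable depth
  d1 <- design_thickness(1e-3, 1, OCR = 0.2, D_material_cm2_s = 2e-5,
                         D_tissue_cm2_s = 2e-5, C_s = 0.2,
                         C_crit_mol_m3 = 0, couple_surface = FALSE)
  expect_equal(d1$L_mm, d1$x_v_mm)
  # quadrupling the cell fraction halves the thickness at fixed C_s
  d4 <- design_thickness(4e-3, 0.9, OCR = 0.2, D_material_cm2_s = 2e-5,
                         D_tissue_cm2_s = 2e-5, C_s = 0.2,
                         C_crit_mol_m3 = 0, couple_surface = FALSE)
  expect_equal(d4$L_mm, d$L_mm / 2, tolerance = 1e-6)
})

test_that("design curves fall log-log linearly with slope -1/2 at fixed C_s", {
  cells <- 10^seq(5.5, 7.5, length.out = 9)
  dc <- design_curve(cells, OCR = 0.034, D_material_cm2_s = 2.4e-5,
                     D_tissue_cm2_s = 2.4e-5, C_s = 0.15,
                     C_crit_mol_m3 = 0, couple_surface = FALSE)
  expect_s3_class(dc, "design_curve")
  expect_true(all(diff(dc$L_mm) < 0))
  slopes <- diff(log(dc$L_mm)) / diff(log(dc$X))
  expect_equal(slopes, rep(-0.5, 8), tolerance = 1e-9)
  # coupled mode gives thinner slabs than the uncoupled ambient surface
  dcc <- design_curve(cells, OCR = 0.034, D_material_cm2_s = 2.4e-5,
                      C_amb = 0.159, couple_surface = TRUE)
  dcu <- design_curve(cells, OCR = 0.034, D_material_cm2_s = 2.4e-5,
                      C_s = 0.159, couple_surface = FALSE)
  expect_true(all(dcc$L_mm <= dcu$L_mm + 1e-12))
})

test_that("dimensionless report is internally consistent", {
  rp <- dimensionless_report(L_mm = 3.5, X = 2.04e-3, OCR = 0.129,
                             D_material_cm2_s = 2.4e-5, C_s = 0.15,
                             u = 1e-7)
  expect_true(rp$eta <= 1 && rp$eta >= 0)
  expect_equal(rp$eta == 1, rp$phi <= rp$phi_crit)
  expect_equal(rp$inputs$D_eff_cm2_s,
               effective_diffusivity(2.04e-3, 1.24e-5, 2.4e-5))
  expect_output(print(rp), "phi")
})

test_that("dimensionless numbers are invariant to consistent unit rescaling", {
  # Pe: mm+cm^2/s inputs versus an all-SI evaluation done by hand
  expect_equal(as.numeric(peclet(2e-6, 3.5, 2.4e-5)),
               2e-6 * 3.5e-3 / 2.4e-9, tolerance = 1e-12)
  # phi: rescaling D and C_s by the same factor leaves k_v/(D C_s) ratios
  phi_a <- thiele_modulus(3.5, 0.01, 0.129, 2.4e-5, 0.15)
  phi_b <- thiele_modulus(3.5, 0.01, 0.129 * 4, 2.4e-5 * 2, 0.15 * 2)
  expect_equal(phi_a, phi_b, tolerance = 1e-12)
})
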