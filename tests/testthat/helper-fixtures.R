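# shared test helpers: coarse solver settings and short synthetic specs keep
# unit tests fast; full-resolution runs live in the acceptance tests

quick_settings <- solver_settings(dz_mm = 0.05, dt_s = 2)

# short noise-free water-geometry spec (1 h, 10 s sampling)
quick_water_spec <- function(D = 3.1e-5, noise_sd = 0, seed = 1L,
                             duration_s = 3600) {
  stack <- layer_stack(4, D, probe_height_mm = 1.8)
  C0 <- convert_oxygen(o2(100, "percent_air_saturation"), "mol_m3")$value
  synthetic_spec(stack, boundary_driver("fopdt", C0 = C0, C_final = 0),
                 sampling_interval_s = 10, duration_s = duration_s,
                 noise_sd = noise_sd, seed = seed,
                 settings = quick_settings)
}

quick_gel_spec <- function(D_gel = 2.4e-5, noise_sd = 0, seed = 1L) {
  stack <- geometry_preset("gel", D_cm2_s = D_gel)
  C0 <- convert_oxygen(o2(100, "percent_air_saturation"), "mol_m3")$value
  synthetic_spec(stack, boundary_driver("fopdt", C0 = C0, C_final = 0),
                 sampling_interval_s = 10, duration_s = 3600,
                 noise_sd = noise_sd, seed = seed,
                 settings = quick_settings)
}

# slab with explicit transport parameters (D_tissue tied to D_gel so
# D_eff == D_gel regardless of X, convenient for closed-form checks)
plain_slab <- function(L_mm = 3.5, k_v = 2e-4, D = 2e-5, C_crit = 0) {
  cellular_slab(L_mm, X = 0.5, OCR = 2 * k_v, D_gel_cm2_s = D,
                D_tissue_cm2_s = D, C_crit_mol_m3 = C_crit)
}
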