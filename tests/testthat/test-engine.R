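test_that("sequence timing follows the editing-pulse placement rules", {
  tm <- compute_timing(64, 16)
  expect_equal(tm$t_refoc1, 8)
  expect_equal(tm$t_edit1, 20)
  expect_equal(tm$t_refoc2, 40)
  expect_equal(tm$t_edit2, 52)
  expect_equal(tm$t_acq, 64)
  # editing-pulse separation is te/2 regardless of te1
  for (te1 in c(10, 16, 20)) {
    tm <- compute_timing(68, te1)
    expect_equal(tm$t_edit2 - tm$t_edit1, 34)
  }
  expect_error(compute_timing(64, 64), "te1")
  expect_error(compute_timing(64, 0), "te1")
  # overlapping pulse intervals are rejected with the colliding pair named
  expect_error(compute_timing(60, 24, edit_ms = 15, refoc_ms = 6),
               "refoc1 and edit1")
})

test_that("simulation grid invariants hold", {
  g <- sim_grid(36, 19, 30)
  expect_equal(length(g$positions_mm), 19)
  expect_equal(g$positions_mm[10], 0)   # centre point exists
  expect_error(sim_grid(36, 10, 30), "odd")
  expect_error(sim_grid(20, 9, 30))
  expect_equal(sim_grid(36, 1, 30)$positions_mm, 0)
})

test_that("Gly is TE-independent and peaks at 3.55 ppm", {
  fids <- simulate_te_series(fx_systems()$Gly, seq(60, 88, 4),
                             edit_condition("OFF"), te1 = 16,
                             edit_pulse = fx_edit_pulse(),
                             mode = "ideal-localized")
  ints <- vapply(fids, function(f) {
    sum(Re(fid_to_spectrum(f, lb_hz = 3)$values))
  }, numeric(1))
  expect_lt(diff(range(ints)) / mean(ints), 0.01)
  sp <- fid_to_spectrum(fids[[1]], lb_hz = 3)
  peak_ppm <- sp$ppm[which.max(Re(sp$values))]
  expect_lt(abs(peak_ppm - 3.55), 2000 / 2048 / fx_ctx()$f0_mhz + 0.003)
})

test_that("FIDs are linear in concentration and normalized per proton", {
  # mixture FID equals the concentration-weighted sum of component FIDs
  sys <- fx_systems()
  f_gly <- simulate_fid(sys$Gly, compute_timing(64), edit_condition("OFF"),
                        edit_pulse = fx_edit_pulse(), mode = "ideal-localized")
  f_thr <- simulate_fid(sys$Thr, compute_timing(64), edit_condition("OFF"),
                        edit_pulse = fx_edit_pulse(), mode = "ideal-localized")
  mix <- 2 * f_gly$samples + 0.5 * f_thr$samples
  s_mix <- combine_metabolites(
    list(Gly = fid_to_spectrum(f_gly), Thr = fid_to_spectrum(f_thr)),
    c(Gly = 2, Thr = 0.5))
  f_mix <- f_gly; f_mix$samples <- mix
  expect_equal(s_mix$values, fid_to_spectrum(f_mix)$values, tolerance = 1e-12)
  # two uncoupled protons: first FID point has magnitude 2 (per-proton scale)
  expect_equal(Mod(f_gly$samples[1]), 2, tolerance = 1e-6)
})

test_that("editing far off-resonance is a no-op (ON equals OFF)", {
  sys <- fx_systems()$GABA
  far_on <- simulate_fid(sys, compute_timing(68), edit_condition("ON", -30),
                         edit_pulse = fx_edit_pulse(), mode = "ideal-localized")
  far_off <- simulate_fid(sys, compute_timing(68), edit_condition("OFF", -34),
                          edit_pulse = fx_edit_pulse(), mode = "ideal-localized")
  expect_lt(max(Mod(far_on$samples - far_off$samples)) / max(Mod(far_off$samples)),
            1e-5)
})

test_that("GABA editing produces an edited multiplet at 3 ppm at TE 68", {
  ed <- fx_gaba_edited()
  d <- ed$on$te68
  d$samples <- d$samples - ed$off$te68$samples
  sp <- fid_to_spectrum(d, lb_hz = 6)
  expect_gt(gaba_edited_area(sp), 0)
  idx <- glymega:::ppm_window(sp, 2.79, 3.28)
  out <- glymega:::ppm_window(sp, 3.6, 4.2)
  expect_gt(max(Re(sp$values[idx])), 5 * max(abs(Re(sp$values[out]))))
})

test_that("two-spin echo follows the analytic cos(pi J TE) modulation", {
  # weakly coupled pair, ideal pulses, editing disabled. The first acquired
  # point equals the summed doublet line amplitude: antiphase terms contribute
  # exactly zero there, so Re FID(0) / n = cos(pi J TE) without lineshape
  # cross-talk between the doublet components.
  ax <- fx_ax_pair()
  tes <- c(20, 40, 100, 120)  # away from the cos zero-crossing at 71 ms
  fids <- simulate_te_series(ax, tes, edit_condition("NONE"), te1 = 10,
                             mode = "ideal-localized")
  amp <- vapply(fids, function(f) Re(f$samples[1]) / 2, numeric(1))
  expect_equal(amp, cos(pi * 7 * tes / 1000), tolerance = 0.02,
               ignore_attr = TRUE)
})

test_that("a single-point shaped grid reproduces the ideal-localized signal", {
  sys <- fx_systems()$mI
  ideal <- simulate_fid(sys, compute_timing(64), edit_condition("OFF"),
                        edit_pulse = fx_edit_pulse(), mode = "ideal-localized")
  # high-bandwidth refocusing pulse: essentially flat at slice centre
  shaped <- simulate_fid(sys, compute_timing(64), edit_condition("OFF"),
                         grid = sim_grid(36, 1, 30),
                         edit_pulse = fx_edit_pulse(),
                         refoc_pulse = make_refocusing_pulse(2, 16, 64),
                         mode = "shaped-refocus")
  num <- max(Mod(shaped$samples - ideal$samples))
  expect_lt(num / max(Mod(ideal$samples)), 0.03)
})

test_that("TE series bookkeeping matches the single-shot simulator", {
  sys <- fx_systems()$Gly
  series <- simulate_te_series(sys, seq(60, 88, 2), edit_condition("OFF"),
                               mode = "ideal-localized",
                               edit_pulse = fx_edit_pulse())
  expect_length(series, 15)
  single <- simulate_te_series(sys, 68, edit_condition("OFF"),
                               mode = "ideal-localized",
                               edit_pulse = fx_edit_pulse())
  direct <- simulate_fid(sys, compute_timing(68), edit_condition("OFF"),
                         edit_pulse = fx_edit_pulse(), mode = "ideal-localized")
  expect_equal(single$te68$samples, direct$samples, tolerance = 1e-12)
  expect_error(simulate_te_series(sys, c(68, 64), edit_condition("OFF")),
               "ascending")
  # propagators are unitary
  setup <- glymega:::megapress_setup(sys, edit_condition("ON"),
                                     mode = "ideal-localized",
                                     edit_pulse = fx_edit_pulse())
  U <- setup$U_edit
  expect_lt(max(Mod(U %*% Conj(t(U)) - diag(nrow(U)))), 1e-10)
})
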