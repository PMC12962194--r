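test_that("apodization adds exactly its width to a Lorentzian line", {
  # FID exp(-pi w t) exp(2i pi f t), lb 3 Hz -> FWHM w + 3 Hz (within 5%)
  fid <- lorentz_fid(w_hz = 4, f_hz = 140)
  sp <- fid_to_spectrum(fid, lb_hz = 3, zerofill_to = 8192)
  peak_ppm <- sp$ppm[which.max(Re(sp$values))]
  expect_equal(measure_fwhm(sp, peak_ppm), 7, tolerance = 0.05)
  # pure 5 Hz Lorentzian measures 5 Hz
  sp5 <- fid_to_spectrum(lorentz_fid(5, 140), zerofill_to = 8192)
  expect_equal(measure_fwhm(sp5, sp5$ppm[which.max(Re(sp5$values))]), 5,
               tolerance = 0.05)
  # all-zero FID -> all-zero spectrum
  z <- lorentz_fid(1, 0, amp = 0)
  expect_true(all(fid_to_spectrum(z)$values == 0))
  expect_error(fid_to_spectrum(fid, zerofill_to = 1024), "zerofill")
})

test_that("transform conserves energy and apodization is monotone", {
  fid <- lorentz_fid(3, 222)
  sp <- fid_to_spectrum(fid)
  e_time <- sum(Mod(fid$samples)^2)
  e_freq <- sum(Mod(sp$values)^2) / length(sp$values)
  expect_equal(e_time, e_freq, tolerance = 1e-10)
  peaks <- c(); widths <- c()
  for (lb in c(0, 2, 5, 10)) {
    s <- fid_to_spectrum(fid, lb_hz = lb, zerofill_to = 8192)
    peaks <- c(peaks, max(Re(s$values)))
    widths <- c(widths, measure_fwhm(s, s$ppm[which.max(Re(s$values))]))
  }
  expect_true(all(diff(peaks) < 0))
  expect_true(all(diff(widths) > 0))
})

test_that("SNR measurement follows the Cr-peak over 10-12 ppm noise definition", {
  # Cr-like singlet at 3.03 ppm
  f0 <- fx_ctx()$f0_mhz
  fid <- lorentz_fid(4, (4.65 - 3.03) * f0, amp = 5)
  clean <- fid_to_spectrum(fid)
  expect_equal(measure_snr(clean), Inf)
  noisy <- add_noise_to_snr(clean, target_snr = 247, seed = 7)
  expect_equal(measure_snr(noisy), 247, tolerance = 0.1)
  # determinism and the noise-off switch
  noisy2 <- add_noise_to_snr(clean, target_snr = 247, seed = 7)
  expect_identical(noisy$values, noisy2$values)
  expect_identical(add_noise_to_snr(clean, Inf, 1)$values, clean$values)
  expect_error(add_noise_to_snr(clean, -5, 1), "positive")
  # pure noise still yields a positive (max-statistic) SNR
  pure <- clean; pure$values <- complex(length(clean$values))
  pure_n <- add_noise_to_snr(fid_to_spectrum(lorentz_fid(4, (4.65 - 3.03) * f0,
                                                         amp = 1e-9)),
                             target_snr = 1e-9, seed = 3)
  expect_gt(measure_snr(pure_n), 0)
})

test_that("noise injection preserves the expected spectrum", {
  f0 <- fx_ctx()$f0_mhz
  clean <- fid_to_spectrum(lorentz_fid(4, (4.65 - 3.03) * f0, n = 512, amp = 5))
  probes <- glymega:::ppm_window(clean, 2.9, 3.1)[1:5]
  reps <- vapply(1:100, function(s) {
    Re(add_noise_to_snr(clean, 50, seed = s)$values[probes])
  }, numeric(5))
  mn <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(mn - Re(clean$values[probes])) < 3 * se + 1e-12))
})

test_that("linewidth matching reaches the target width", {
  f0 <- fx_ctx()$f0_mhz
  sp <- fid_to_spectrum(lorentz_fid(2, (4.65 - 2.0) * f0), zerofill_to = 4096)
  b5 <- broaden_to_linewidth(sp, 5, 2.0)
  expect_equal(measure_fwhm(b5, 2.0), 5, tolerance = 0.05)
  b10 <- broaden_to_linewidth(b5, 10, 2.0)
  expect_equal(measure_fwhm(b10, 2.0), 10, tolerance = 0.05)
  expect_equal(b10$meta$lb_hz - b5$meta$lb_hz, 5, tolerance = 1)
  # target equal to current width: unchanged
  cur <- measure_fwhm(b5, 2.0)
  expect_identical(broaden_to_linewidth(b5, cur, 2.0)$values, b5$values)
  expect_error(broaden_to_linewidth(b10, 5, 2.0), "exceeds")
})

test_that("metabolite combination is linear with concentration", {
  lib <- fx_unit_lib()
  sp <- list(Gly = lib$Gly$OFF$te64, Cr = lib$Cr$OFF$te64)
  both <- combine_metabolites(sp, c(Gly = 1, Cr = 2))
  no_gly <- combine_metabolites(sp, c(Gly = 0, Cr = 2))
  only_cr <- combine_metabolites(sp, c(Cr = 2))
  expect_equal(no_gly$values, only_cr$values, tolerance = 1e-12)
  dbl <- combine_metabolites(sp, c(Gly = 2, Cr = 4))
  expect_equal(dbl$values, 2 * both$values, tolerance = 1e-12)
  short <- sp$Gly; short$ppm <- short$ppm + 0.001
  expect_error(combine_metabolites(list(Gly = short, Cr = sp$Cr),
                                   c(Gly = 1, Cr = 1)), "grid")
})

test_that("zero-order phasing conventions behave", {
  f0 <- fx_ctx()$f0_mhz
  fid <- lorentz_fid(4, (4.65 - 3.03) * f0, amp = 5)
  fid$samples <- fid$samples * exp(1i * 0.7)
  sp <- fid_to_spectrum(fid)
  ph <- phase_spectrum(sp, "first-point")
  expect_gt(max(Re(ph$values)), 0.99 * max(Mod(ph$values)))
  ph2 <- phase_spectrum(sp, "search")
  expect_gt(max(Re(ph2$values)), 0.95 * max(Mod(ph2$values)))
})
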