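test_that("cohort has the full subject x TE x condition layout", {
  coh <- fx_cohort()
  expect_length(coh$spectra, 6)
  for (subj in coh$spectra) {
    expect_named(subj, c("te64", "te68"))
    for (te in subj) {
      expect_named(te, c("ON", "OFF", "SUM", "DIFF"))
      # SUM and DIFF are exact pointwise combinations
      expect_equal(te$SUM$values, te$ON$values + te$OFF$values,
                   tolerance = 1e-12)
      expect_equal(te$DIFF$values, te$ON$values - te$OFF$values,
                   tolerance = 1e-12)
    }
  }
  # truth is recorded with seeds
  expect_true(all(vapply(coh$subjects, function(s) length(s$noise_seeds) == 4,
                         logical(1))))
})

test_that("cohort generation is reproducible and hits its SNR targets", {
  lib <- fx_unit_lib()
  cfg <- cohort_config()
  a <- generate_cohort(2, cfg, master_seed = 7, systems = fx_systems(),
                       unit_lib = lib)
  b <- generate_cohort(2, cfg, master_seed = 7, systems = fx_systems(),
                       unit_lib = lib)
  expect_identical(a$spectra$S01$te64$OFF$values, b$spectra$S01$te64$OFF$values)
  expect_identical(a$subjects[[2]]$concentrations,
                   b$subjects[[2]]$concentrations)
  c2 <- generate_cohort(2, cfg, master_seed = 8, systems = fx_systems(),
                        unit_lib = lib)
  expect_false(identical(a$spectra$S01$te64$OFF$values,
                         c2$spectra$S01$te64$OFF$values))
  # SNR within 10% of the configured target; SUM noise ~ sqrt(2) higher
  off <- a$spectra$S01$te64$OFF
  expect_equal(measure_snr(off), cfg$snr_off, tolerance = 0.1)
  nidx <- glymega:::ppm_window(off, 10, 12)
  ratio <- sd(Re(a$spectra$S01$te64$SUM$values[nidx])) /
    sd(Re(off$values[nidx]))
  expect_equal(ratio, sqrt(2), tolerance = 0.05)
  # linewidth lands near its target
  expect_equal(measure_fwhm(off, 2.0), a$subjects[[1]]$linewidth_hz,
               tolerance = 0.1)
})

test_that("noiseless cohort concentrations are recovered within 1%", {
  coh <- generate_cohort(2, cohort_config(), master_seed = 21,
                         systems = fx_systems(), unit_lib = fx_unit_lib(),
                         noise = FALSE)
  basis <- cohort_basis(coh, 64, "OFF")
  for (i in 1:2) {
    rec <- coh$spectra[[i]]$te64
    b <- match_basis_linewidth(basis, rec$OFF)
    fit <- fit_lcm(rec$OFF, b)
    truth <- coh$subjects[[i]]$concentrations
    for (m in c("Gly", "mI", "Glc", "Cr", "NAA")) {
      expect_equal(unname(coef(fit)[m]), unname(truth[m]), tolerance = 0.01,
                   label = sprintf("subject %d %s", i, m))
    }
  }
})

test_that("sum_and_diff validates pairing and has the variance-addition property", {
  lib <- fx_unit_lib()
  on <- lib$GABA$ON$te64
  off <- lib$GABA$OFF$te64
  same <- sum_and_diff(on, on)
  expect_true(all(same$DIFF$values == 0))
  off68 <- lib$GABA$OFF$te68
  expect_error(sum_and_diff(on, off68), "pairing")
  # independent unit-noise pair: SUM noise SD = sqrt(2) x single (5% at 2048)
  z <- off; z$values <- complex(length(off$values))
  n1 <- glymega:::add_noise_sigma(z, 1e-3, 101)
  n2 <- glymega:::add_noise_sigma(z, 1e-3, 102)
  sd_pair <- sum_and_diff(n1, n2)
  expect_equal(sd(Re(sd_pair$SUM$values)) / sd(Re(n1$values)), sqrt(2),
               tolerance = 0.05)
})

test_that("CV definitions match their hand-computed examples", {
  expect_equal(between_acquisition_cv(1, 1), 0)
  expect_equal(between_acquisition_cv(0.8, 1.2), 40)
  expect_true(is.na(between_acquisition_cv(-1, 1)))
  expect_equal(inter_subject_cv(c(5, 5, 5)), 0)
  expect_equal(inter_subject_cv(c(1, 2, 3)), 50)
  expect_error(inter_subject_cv(3), "two")
})

test_that("Mann-Whitney U matches exact enumeration and the wilcox oracle", {
  # identical multisets: p = 1
  expect_equal(mann_whitney_u(c(1, 2, 2), c(2, 1, 2))$p, 1)
  # complete separation at n = m = 6: p = 2 / choose(12, 6)
  r <- mann_whitney_u(1:6, 7:12)
  expect_equal(r$p, 2 / choose(12, 6), tolerance = 1e-12)
  expect_equal(r$method, "exact enumeration")
  # U + U' = n m
  set.seed(31)
  for (k in 1:5) {
    a <- rnorm(5); b <- rnorm(7)
    expect_equal(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U, 35)
    # tie-free small samples agree with the exact wilcox.test oracle
    w <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mann_whitney_u(a, b)$U, unname(w$statistic))
    expect_equal(mann_whitney_u(a, b)$p, w$p.value, tolerance = 1e-12)
  }
  # large samples switch to the normal approximation and stay in [0, 1]
  big <- mann_whitney_u(rnorm(60), rnorm(60) + 0.2)
  expect_equal(big$method, "normal approximation")
  expect_true(big$p >= 0 && big$p <= 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("3.55 ppm peak height grows monotonically with Gly concentration", {
  # Fig-3-style series: TE 64, ~5 Hz linewidth, mI at 3 mM, Gly 0-3 mM
  lib <- fx_unit_lib()
  cfg <- cohort_config()
  conc <- cfg$conc_mean
  conc["mI"] <- 3
  heights <- vapply(c(0, 0.5, 1, 2, 3), function(g) {
    conc["Gly"] <- g
    mix <- combine_metabolites(lapply(lib, function(l) l$OFF$te64), conc)
    mix <- broaden_to_linewidth(mix, 5, 2.0)
    max(Re(mix$values[glymega:::ppm_window(mix, 3.53, 3.57)]))
  }, numeric(1))
  expect_true(all(diff(heights) > 0))
})

test_that("cohort report computes CVs, rank-sum tests and the Gly comparison", {
  rep_ <- fx("cohort_report", function() cohort_report(fx_cohort()))
  expect_equal(nrow(rep_$fits), 12)
  expect_equal(sort(unique(rep_$fits$te)), c(64, 68))
  expect_true(all(rep_$fits$cv_gly >= 0))
  expect_true(all(is.finite(rep_$cv$inter_subject_cv_off)))
  expect_true(all(vapply(rep_$tests, function(t) t$p >= 0 && t$p <= 1,
                         logical(1))))
  # Gly estimates track the generating truth (noisy, so loosely)
  expect_equal(mean(rep_$fits$gly_off), mean(rep_$fits$gly_true),
               tolerance = 0.1)
  expect_equal(nrow(rep_$gly_comparison), 24)  # 6 subjects x 2 TE x 2 acq
})
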