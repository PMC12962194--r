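test_that("basis construction respects conditions and rejects bad requests", {
  coh <- fx_cohort()
  b_off <- cohort_basis(coh, 64, "OFF")
  b_sum <- cohort_basis(coh, 64, "SUM")
  # NAA 2.0 ppm response attenuated in SUM (ON pulse at 1.9 saturates it)
  naa_off <- max(Re(b_off$spectra$NAA$values[
    glymega:::ppm_window(b_off$spectra$NAA, 1.95, 2.05)]))
  naa_sum <- max(Re(b_sum$spectra$NAA$values[
    glymega:::ppm_window(b_sum$spectra$NAA, 1.95, 2.05)]))
  expect_lt(naa_sum, 1.7 * naa_off)  # far below the 2x of an untouched spin
  # Gly untouched by either editing pulse: SUM response ~ 2x OFF
  gly_off <- max(Re(b_off$spectra$Gly$values))
  gly_sum <- max(Re(b_sum$spectra$Gly$values))
  expect_equal(gly_sum / gly_off, 2, tolerance = 0.02)
  expect_error(cohort_basis(coh, 64, "OFF", metabolites = c("Gly", "Nope")),
               "unknown")
  expect_error(build_basis(fx_systems(), c("Gly", "Gly"), 64), "duplicate")
  expect_error(build_basis(fx_systems(), "Creatinine", 64), "unknown")
})

test_that("noiseless self-representation is recovered exactly", {
  coh <- fx_cohort()
  basis <- fx_basis64_off()
  truth <- c(Gly = 0.9, mI = 3.3, Glc = 1.7, Thr = 0.3, GABA = 1.4,
             Cr = 8.0, NAA = 12.0)
  mix <- combine_metabolites(basis$spectra, truth)
  fit <- fit_lcm(mix, basis)
  expect_equal(unname(coef(fit)[names(truth)]), unname(truth),
               tolerance = 1e-3)
  # single component times 3: that concentration is 3, all others 0
  one <- basis$spectra$Cr
  one$values <- 3 * one$values
  fit1 <- fit_lcm(one, basis)
  expect_equal(unname(coef(fit1)["Cr"]), 3, tolerance = 1e-3)
  expect_lt(max(coef(fit1)[setdiff(names(coef(fit1)), "Cr")]), 1e-3)
  # residual of a perfect fit is ~0 and the residual window must be inside
  expect_lt(residual_rms(fit), 1e-6 * max(Re(mix$values)))
  expect_error(residual_rms(fit, 0.1, 3.7), "outside")
})

test_that("fit is idempotent on its own prediction", {
  coh <- fx_cohort()
  basis <- fx_basis64_off()
  spec <- coh$spectra$S02$te64$OFF
  b <- match_basis_linewidth(basis, spec)
  fit <- fit_lcm(spec, b)
  pred <- spec
  idx <- fit$design$idx
  pred$values[idx] <- complex(real = fitted(fit))
  refit <- fit_lcm(pred, b)
  expect_equal(coef(refit), coef(fit), tolerance = 1e-4)
})

test_that("CRLB follows the closed-form single-parameter bound and scaling law", {
  # craft a basis whose single column is unit-norm and zero-mean (orthogonal
  # to the flat baseline) over the fit window
  n <- 2048
  ppm <- seq(12.4, -3.2, length.out = n)
  idx <- which(ppm >= 0.2 & ppm <= 4.2)
  v <- sin(seq(0, 40 * pi, length.out = length(idx)))
  v <- v / sqrt(sum(v^2))
  base_spec <- function(vals) {
    structure(list(ppm = ppm, values = complex(real = vals),
                   meta = list(f0_mhz = 127.73, center_ppm = 4.65,
                               n_acquired = n, dwell = 1 / 2000)),
              class = "spectrum")
  }
  col <- numeric(n); col[idx] <- v
  basis <- structure(list(names = "X", spectra = list(X = base_spec(col)),
                          te = 64, condition = "OFF", lb_hz = 0),
                     class = "basis_set")
  sigma <- 0.05; conc <- 3
  noise <- with_seed(11, rnorm(n, 0, sigma))
  data <- base_spec(conc * col + noise)
  fit <- fit_lcm(data, basis, baseline_order = 1)
  expect_equal(unname(fit$crlb_pct["X"]), 100 * fit$noise_sd / conc,
               tolerance = 0.05)
  # doubling sigma doubles every CRLB%
  fit2 <- fit
  fit2$noise_sd <- 2 * fit$noise_sd
  expect_equal(compute_crlb(fit2, basis), 2 * compute_crlb(fit, basis),
               tolerance = 1e-12)
  # adding an orthogonal component never decreases the first component's CRLB
  set.seed(5)
  for (r in 1:5) {
    w <- rnorm(length(idx)); w <- w - sum(w * v) * v
    w <- w / sqrt(sum(w^2))
    col2 <- numeric(n); col2[idx] <- w
    basis2 <- basis
    basis2$names <- c("X", "Y")
    basis2$spectra$Y <- base_spec(col2)
    fitb <- fit_lcm(data, basis2, baseline_order = 1)
    expect_gte(fitb$crlb_pct[["X"]] * 1.0001, fit$crlb_pct[["X"]])
  }
})

test_that("Gly omission is harmless when no Gly was generated", {
  coh <- fx_cohort()
  basis <- fx_basis64_off()
  truth <- c(Gly = 0, mI = 3.3, Glc = 1.7, Cr = 8.0, NAA = 12.0)
  mix <- combine_metabolites(basis$spectra, truth)
  mix <- glymega:::add_noise_sigma(mix, glymega:::cohort_noise_sigma(mix, 247), 99)
  tbl <- gly_inclusion_experiment(list(mix), basis)
  expect_equal(nrow(tbl), 1)
  expect_equal(tbl$gly_minus_rms / tbl$gly_plus_rms, 1, tolerance = 0.05)
})

test_that("Gaussian difference-peak fitter recovers known parameters", {
  n <- 2048
  ppm <- seq(12.4, -3.2, length.out = n)
  truth <- list(a = 4, mu = 3.02, sg = 0.05, sl = 0.3, off = -0.5)
  vals <- truth$a * exp(-(ppm - truth$mu)^2 / (2 * truth$sg^2)) +
    truth$sl * ppm + truth$off
  spec <- structure(list(ppm = ppm, values = complex(real = vals),
                         meta = list(f0_mhz = 127.73, center_ppm = 4.65)),
                    class = "spectrum")
  g <- fit_gaba_diff(spec)
  expect_true(g$converged)
  expect_equal(g$amplitude, truth$a, tolerance = 1e-5)
  expect_equal(g$center_ppm, truth$mu, tolerance = 1e-6)
  expect_equal(g$sigma_ppm, truth$sg, tolerance = 1e-5)
  # analytic-area invariant
  expect_equal(g$area, g$amplitude * g$sigma_ppm * sqrt(2 * pi),
               tolerance = 1e-12)
  # a featureless spectrum raises the failure flag with parameters absent
  flat <- spec; flat$values <- complex(real = rep(0.2, n))
  gf <- fit_gaba_diff(flat)
  expect_false(gf$converged)
  expect_true(is.na(gf$area))
})
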