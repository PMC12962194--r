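#' Build a simulated basis set
#'
#' Simulates unit-concentration metabolite responses at the requested TE and
#' acquisition condition on a common spectral grid. `condition = "SUM"` builds
#' the ON + OFF response (the SUM spectrum contains twice the transients, so
#' its basis is the pointwise sum of the two conditions).
#'
#' @param systems Named list of [spin_system()] objects.
#' @param metabolites Character vector of metabolite names (no duplicates).
#' @param te Echo time, ms.
#' @param condition `"OFF"` or `"SUM"`.
#' @param lb_hz Apodization of the basis responses, Hz (default 2; the fitting
#'   pipeline broadens further to match the data, see
#'   [match_basis_linewidth()]).
#' @param zerofill_to Zero-fill length (default 4096, the fitting pipeline
#'   convention).
#' @param te1 PRESS sub-echo time, ms.
#' @param mode Simulation mode (default `"ideal-localized"`; the fitter tests
#'   target estimation behaviour, not localization).
#' @param ctx A [spectrometer_context()].
#' @param ... Further arguments to [simulate_metabolite_series()].
#' @return Object of class `basis_set`: `names`, `spectra` (named list of
#'   unit-concentration `spectrum`), `te`, `condition`, `lb_hz`.
#' @export
build_basis <- function(systems, metabolites, te, condition = c("OFF", "SUM"),
                        lb_hz = 2, zerofill_to = 4096, te1 = 16,
                        mode = "ideal-localized",
                        ctx = spectrometer_context(), ...) {
  condition <- match.arg(condition)
  if (anyDuplicated(metabolites)) {
    stop("duplicate metabolite names in basis request: ",
         paste(unique(metabolites[duplicated(metabolites)]), collapse = ", "))
  }
  known <- unique(vapply(systems, function(s) s$metabolite, character(1)))
  missing <- setdiff(metabolites, known)
  if (length(missing)) stop("unknown metabolite(s): ", paste(missing, collapse = ", "))
  conds <- if (condition == "OFF") "OFF" else c("ON", "OFF")
  spectra <- lapply(metabolites, function(m) {
    fids <- lapply(conds, function(cl) {
      simulate_metabolite_series(systems, m, te, edit_condition(cl), te1 = te1,
                                 mode = mode, ctx = ctx, ...)[[1]]
    })
    fid <- fids[[1]]
    if (length(fids) > 1) fid$samples <- fid$samples + fids[[2]]$samples
    fid$meta$condition <- condition
    fid_to_spectrum(fid, lb_hz = lb_hz, zerofill_to = zerofill_to, ctx = ctx)
  })
  names(spectra) <- metabolites
  structure(list(names = metabolites, spectra = spectra, te = te,
                 condition = condition, lb_hz = lb_hz),
            class = "basis_set")
}

#' @export
print.basis_set <- function(x, ...) {
  cat(sprintf("<basis_set> %s at TE %g ms: %s\n", x$condition, x$te,
              paste(x$names, collapse = ", ")))
  invisible(x)
}

#' Drop a component from a basis set
#'
#' @param basis A `basis_set`.
#' @param name Metabolite to remove.
#' @return The reduced `basis_set`.
#' @export
drop_component <- function(basis, name) {
  if (!(name %in% basis$names)) stop("'", name, "' is not in the basis")
  basis$names <- setdiff(basis$names, name)
  basis$spectra[[name]] <- NULL
  basis
}

#' Match basis linewidth to the data
#'
#' Broadens every basis response so that the creatine-region FWHM of the basis
#' matches the NAA linewidth measured on the data spectrum (the package's
#' single-lineshape simplification; no per-metabolite lineshape parameters).
#'
#' @param basis A `basis_set` containing Cr.
#' @param spectrum The data `spectrum` (must contain NAA at 2.0 ppm).
#' @return The broadened `basis_set`.
#' @export
match_basis_linewidth <- function(basis, spectrum) {
  if (!("Cr" %in% basis$names)) stop("basis must contain Cr to match linewidth")
  data_fwhm <- measure_fwhm(spectrum, 2.0)
  cr <- basis$spectra$Cr
  if (data_fwhm - measure_fwhm(cr, 3.027) <= 0.05 * data_fwhm) return(basis)
  # calibrate the extra broadening on the Cr response, then apply it everywhere
  cr_b <- broaden_to_linewidth(cr, data_fwhm, 3.027)
  lb <- (cr_b$meta$lb_hz %||% 0) - (cr$meta$lb_hz %||% 0)
  basis$spectra <- lapply(basis$spectra, apodize_spectrum, lb_hz = lb)
  basis$lb_hz <- basis$lb_hz + lb
  basis
}

#' Linear-combination fit of a spectrum
#'
#' Fits the real part of the spectrum over `fit_window` as a non-negative
#' linear combination of the basis responses plus an unconstrained polynomial
#' baseline. The baseline is profiled out exactly, so the returned amplitudes
#' solve the joint non-negative least-squares problem; a small ridge penalty
#' (`ridge_frac` times the mean squared basis norm) stabilizes collinear pairs
#' rather than excluding them. Cramer-Rao lower bounds are computed from the
#' Fisher information of the full design (basis plus baseline columns) with
#' the noise variance estimated from the 10-12 ppm region.
#'
#' @param spectrum A `spectrum` on the same ppm grid as the basis.
#' @param basis A [build_basis()] result.
#' @param baseline_order Polynomial baseline order (default 4).
#' @param fit_window Fit interval in ppm (default `c(0.2, 4.2)`).
#' @param ridge_frac Relative ridge weight (default 1e-6).
#' @return Object of class `lc_fit`: `concentrations` (institutional units,
#'   equal to mM when data and basis share scaling), `crlb_pct`, `baseline`
#'   coefficients, `residual` (spectrum over the fit window), `noise_sd`,
#'   `fit_window`.
#' @export
#' @examples
#' # see the package tests for a full synthetic-mixture example
fit_lcm <- function(spectrum, basis, baseline_order = 4,
                    fit_window = c(0.2, 4.2), ridge_frac = 1e-6) {
  stopifnot(inherits(spectrum, "spectrum"), inherits(basis, "basis_set"))
  ref <- basis$spectra[[1]]
  if (length(ref$ppm) != length(spectrum$ppm) ||
      max(abs(ref$ppm - spectrum$ppm)) > 1e-9) {
    stop("basis and data are not on the same ppm grid")
  }
  idx <- ppm_window(spectrum, fit_window[1], fit_window[2])
  y <- Re(spectrum$values[idx])
  B <- vapply(basis$spectra, function(s) Re(s$values[idx]), numeric(length(idx)))
  x <- (spectrum$ppm[idx] - mean(fit_window)) / (diff(fit_window) / 2)
  P <- cbind(1, stats::poly(x, degree = baseline_order, raw = FALSE))
  # profile out the baseline: project y and B onto the orthocomplement of P
  qP <- qr(P)
  Qy <- y - P %*% qr.coef(qP, y)
  QB <- B - P %*% qr.coef(qP, B)
  lambda <- ridge_frac * mean(colSums(QB^2))
  Aaug <- rbind(QB, sqrt(lambda) * diag(ncol(B)))
  baug <- c(Qy, numeric(ncol(B)))
  alpha <- pracma::lsqnonneg(Aaug, baug)$x
  names(alpha) <- basis$names
  beta <- qr.coef(qP, y - B %*% alpha)
  model <- as.vector(B %*% alpha + P %*% beta)
  resid_spec <- structure(
    list(ppm = spectrum$ppm[idx], values = complex(real = y - model),
         meta = c(spectrum$meta[c("f0_mhz", "center_ppm", "dwell")],
                  list(system = "residual", fit_window = fit_window))),
    class = "spectrum")
  noise_sd <- stats::sd(Re(spectrum$values[ppm_window(spectrum, 10, 12)]))
  fit <- structure(
    list(concentrations = alpha, crlb_pct = NULL, baseline = as.vector(beta),
         residual = resid_spec, noise_sd = noise_sd, fit_window = fit_window,
         model = model, data = y, design = list(B = B, P = P, idx = idx),
         basis_names = basis$names, te = basis$te, condition = basis$condition),
    class = "lc_fit")
  fit$crlb_pct <- compute_crlb(fit, basis)
  fit
}

#' Cramer-Rao lower bounds of a linear-combination fit
#'
#' Fisher information `F = J' J / sigma^2` with `J` the full design matrix
#' (basis and baseline columns) over the fit window; the bound for component i
#' is `100 * sqrt((F^-1)[i, i]) / c_i` percent. Bounds are reported as `NA`
#' for non-positive concentration estimates and `Inf` if the information
#' matrix is numerically singular.
#'
#' @param fit An [fit_lcm()] result.
#' @param basis The `basis_set` used for the fit (names must match).
#' @return Named numeric vector of CRLB percentages.
#' @export
compute_crlb <- function(fit, basis) {
  stopifnot(inherits(fit, "lc_fit"))
  if (!identical(fit$basis_names, basis$names)) {
    stop("basis does not match the one used for the fit")
  }
  J <- cbind(fit$design$B, fit$design$P)
  Fi <- crossprod(J) / fit$noise_sd^2
  nb <- length(fit$basis_names)
  cov <- tryCatch(solve(Fi), error = function(e) NULL)
  out <- rep(Inf, nb)
  names(out) <- fit$basis_names
  if (!is.null(cov)) {
    sdv <- sqrt(pmax(diag(cov)[seq_len(nb)], 0))
    out <- 100 * sdv / fit$concentrations
    out[!(fit$concentrations > 0)] <- NA_real_
    names(out) <- fit$basis_names
  }
  out
}

#' Residual RMS in a ppm window
#'
#' @param fit An `lc_fit`.
#' @param lo_ppm,hi_ppm Window, ppm (defaults 3.4 and 3.7, the Gly fit-quality
#'   window); must lie inside the fit window.
#' @return RMS of the fit residual's real part over the window.
#' @export
residual_rms <- function(fit, lo_ppm = 3.4, hi_ppm = 3.7) {
  stopifnot(inherits(fit, "lc_fit"))
  if (lo_ppm < fit$fit_window[1] || hi_ppm > fit$fit_window[2]) {
    stop(sprintf("window [%g, %g] lies outside the fit window [%g, %g]",
                 lo_ppm, hi_ppm, fit$fit_window[1], fit$fit_window[2]))
  }
  rms_in_window(fit$residual, lo_ppm, hi_ppm)
}

#' @export
print.lc_fit <- function(x, ...) {
  cat(sprintf("<lc_fit> %s at TE %g ms, %d components + order-%d baseline\n",
              x$condition, x$te, length(x$concentrations),
              length(x$baseline) - 1))
  print(round(rbind(concentration = x$concentrations, crlb_pct = x$crlb_pct), 3))
  invisible(x)
}

#' @export
coef.lc_fit <- function(object, ...) object$concentrations

#' @export
residuals.lc_fit <- function(object, ...) Re(object$residual$values)

#' @export
fitted.lc_fit <- function(object, ...) object$model

#' @export
summary.lc_fit <- function(object, ...) {
  df <- data.frame(metabolite = names(object$concentrations),
                   concentration = unname(object$concentrations),
                   crlb_pct = unname(object$crlb_pct))
  structure(list(table = df, noise_sd = object$noise_sd,
                 resid_rms_gly = residual_rms(object)),
            class = "summary.lc_fit")
}

#' @export
print.summary.lc_fit <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("noise SD %.4g; residual RMS (3.4-3.7 ppm) %.4g\n",
              x$noise_sd, x$resid_rms_gly))
  invisible(x)
}

#' Gly inclusion/exclusion comparison
#'
#' Fits every spectrum twice, with the full basis (Gly+) and with Gly removed
#' (Gly-), and tabulates the residual RMS in the 3.4-3.7 ppm window and the
#' mI and Glc CRLBs under both fits — the paired design used to test whether
#' omitting Gly degrades the neighbouring fits.
#'
#' @param spectra List of `spectrum` objects.
#' @param basis A `basis_set` containing Gly (and mI, Glc).
#' @param ... Passed to [fit_lcm()].
#' @return Data frame with one row per spectrum: residual RMS and CRLBs under
#'   Gly+ and Gly-.
#' @export
gly_inclusion_experiment <- function(spectra, basis, ...) {
  if (!("Gly" %in% basis$names)) stop("basis must contain Gly")
  basis_m <- drop_component(basis, "Gly")
  rows <- lapply(seq_along(spectra), function(k) {
    fp <- fit_lcm(spectra[[k]], basis, ...)
    fm <- fit_lcm(spectra[[k]], basis_m, ...)
    data.frame(
      spectrum = k,
      gly_plus_rms = residual_rms(fp), gly_minus_rms = residual_rms(fm),
      mI_crlb_plus = fp$crlb_pct[["mI"]], mI_crlb_minus = fm$crlb_pct[["mI"]],
      Glc_crlb_plus = fp$crlb_pct[["Glc"]], Glc_crlb_minus = fm$crlb_pct[["Glc"]],
      gly_conc = fp$concentrations[["Gly"]]
    )
  })
  do.call(rbind, rows)
}

#' Gaussian fit of the edited GABA+ difference peak
#'
#' Fits `amplitude * exp(-(ppm - center)^2 / (2 sigma^2)) + slope * ppm +
#' offset` to the real part of the difference spectrum over the fit window by
#' nonlinear least squares (with up to three jittered restarts). The reported
#' area is the analytic Gaussian area `amplitude * sigma * sqrt(2 pi)`, and
#' the fit error is `100 * SD(residual) / amplitude`.
#'
#' @param diff_spectrum `spectrum` of the ON - OFF difference.
#' @param window Fit window, ppm (default `c(2.79, 3.55)`).
#' @return Object of class `gaba_fit` with fields `amplitude`, `center_ppm`,
#'   `sigma_ppm`, `baseline_slope`, `baseline_offset`, `area`,
#'   `fit_error_pct`, `converged`.
#' @export
fit_gaba_diff <- function(diff_spectrum, window = c(2.79, 3.55)) {
  idx <- ppm_window(diff_spectrum, window[1], window[2])
  x <- diff_spectrum$ppm[idx]
  y <- Re(diff_spectrum$values[idx])
  start0 <- list(a = max(y) - stats::median(y),
                 mu = x[which.max(y)], sg = 0.04,
                 sl = 0, off = stats::median(y))
  fit <- NULL
  for (try in 1:3) {
    st <- start0
    if (try > 1) {
      st$mu <- st$mu + c(0, -0.02, 0.02)[try]
      st$sg <- st$sg * c(1, 2, 0.5)[try]
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * sg^2)) + sl * x + off,
                        start = st,
                        lower = c(a = 0, mu = window[1], sg = 1e-3,
                                  sl = -Inf, off = -Inf),
                        upper = c(a = Inf, mu = window[2], sg = 0.5,
                                  sl = Inf, off = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    return(structure(list(converged = FALSE, amplitude = NA_real_,
                          center_ppm = NA_real_, sigma_ppm = NA_real_,
                          baseline_slope = NA_real_, baseline_offset = NA_real_,
                          area = NA_real_, fit_error_pct = NA_real_),
                     class = "gaba_fit"))
  }
  cf <- stats::coef(fit)
  structure(
    list(converged = TRUE,
         amplitude = unname(cf["a"]), center_ppm = unname(cf["mu"]),
         sigma_ppm = unname(cf["sg"]), baseline_slope = unname(cf["sl"]),
         baseline_offset = unname(cf["off"]),
         area = unname(cf["a"] * cf["sg"] * sqrt(2 * pi)),
         fit_error_pct = 100 * stats::sd(stats::residuals(fit)) / unname(cf["a"]),
         window = window),
    class = "gaba_fit")
}

#' @export
print.gaba_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<gaba_fit> did not converge\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<gaba_fit> area %.4g at %.3f ppm (sigma %.3f ppm), fit error %.2f%%\n",
    x$area, x$center_ppm, x$sigma_ppm, x$fit_error_pct))
  invisible(x)
}

#' @export
coef.gaba_fit <- function(object, ...) {
  c(amplitude = object$amplitude, center_ppm = object$center_ppm,
    sigma_ppm = object$sigma_ppm, baseline_slope = object$baseline_slope,
    baseline_offset = object$baseline_offset)
}
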