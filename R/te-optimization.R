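#' RMS amplitude in a ppm window
#'
#' Root mean square of the real spectral amplitude over all grid points inside
#' `[lo_ppm, hi_ppm]` — the overlap statistic used to quantify how much signal
#' a nuisance metabolite contributes to the glycine detection window.
#'
#' @param spectrum A `spectrum`.
#' @param lo_ppm,hi_ppm Window bounds, ppm (defaults 3.5 and 3.6, the Gly
#'   window).
#' @return Non-negative scalar, same units as the spectral amplitude.
#' @export
rms_in_window <- function(spectrum, lo_ppm = 3.5, hi_ppm = 3.6) {
  idx <- ppm_window(spectrum, lo_ppm, hi_ppm)
  sqrt(mean(Re(spectrum$values[idx])^2))
}

#' Overlap curve: nuisance RMS in the Gly window across TE
#'
#' For each metabolite's TE series, converts FIDs to spectra (exponential
#' apodization `lb_hz`), scales to the supplied concentration, and computes
#' the 3.5-3.6 ppm RMS per TE. The normalized curve divides every metabolite's
#' RMS by the Gly RMS at the same TE, so Gly is identically 1.
#'
#' @param te_series Named list: metabolite -> list of `simulated_fid` over a
#'   common TE grid (see [simulate_metabolite_series()]). Must include
#'   `"Gly"`.
#' @param concentrations_mM Named concentrations used for scaling, mM.
#' @param lb_hz Apodization applied before the RMS, Hz (default 3).
#' @param window RMS window, ppm.
#' @param ctx A [spectrometer_context()].
#' @return Object of class `overlap_curve`: `te_grid`, `rms` and `normalized`
#'   (metabolite x TE matrices).
#' @export
build_overlap_curve <- function(te_series, concentrations_mM, lb_hz = 3,
                                window = c(3.5, 3.6),
                                ctx = spectrometer_context()) {
  if (!("Gly" %in% names(te_series))) {
    stop("te_series must contain a 'Gly' series for normalization")
  }
  mets <- names(te_series)
  te_grid <- vapply(te_series[[1]], function(f) f$meta$te, numeric(1))
  rms <- matrix(NA_real_, length(mets), length(te_grid),
                dimnames = list(mets, names(te_series[[1]])))
  for (m in mets) {
    series <- te_series[[m]]
    tg <- vapply(series, function(f) f$meta$te, numeric(1))
    if (length(tg) != length(te_grid) || any(tg != te_grid)) {
      stop("metabolite '", m, "' was not simulated on the common TE grid")
    }
    conc <- concentrations_mM[[m]]
    if (is.null(conc)) stop("no concentration supplied for '", m, "'")
    rms[m, ] <- vapply(series, function(f) {
      conc * rms_in_window(fid_to_spectrum(f, lb_hz = lb_hz, ctx = ctx),
                           window[1], window[2])
    }, numeric(1))
  }
  structure(
    list(te_grid = unname(te_grid), rms = rms,
         normalized = sweep(rms, 2, rms["Gly", ], `/`),
         lb_hz = lb_hz, window = window,
         concentrations = as.list(concentrations_mM)),
    class = "overlap_curve"
  )
}

#' @export
print.overlap_curve <- function(x, ...) {
  cat("<overlap_curve> TE", min(x$te_grid), "-", max(x$te_grid), "ms;",
      "metabolites:", paste(rownames(x$rms), collapse = ", "), "\n")
  nuis <- setdiff(rownames(x$rms), "Gly")
  for (m in nuis) {
    cat(sprintf("  %-4s min at TE %g ms; normalized range %.3g-%.3g\n", m,
                x$te_grid[which.min(x$rms[m, ])],
                min(x$normalized[m, ]), max(x$normalized[m, ])))
  }
  invisible(x)
}

#' As a long data frame (te, metabolite, rms, normalized)
#' @param x An `overlap_curve`.
#' @export
as.data.frame.overlap_curve <- function(x, ...) {
  mets <- rownames(x$rms)
  data.frame(
    te = rep(x$te_grid, each = length(mets)),
    metabolite = rep(mets, times = length(x$te_grid)),
    rms = as.vector(x$rms),
    normalized = as.vector(x$normalized)
  )
}

#' Edited GABA area in the difference spectrum
#'
#' Signed trapezoidal integral of the real part of the (ON - OFF) difference
#' spectrum over the edited multiplet window.
#'
#' @param diff_spectrum `spectrum` of the ON - OFF difference.
#' @param lo_ppm,hi_ppm Integration window, ppm (defaults 2.79 and 3.28).
#' @return Signed area in amplitude x ppm units.
#' @export
gaba_edited_area <- function(diff_spectrum, lo_ppm = 2.79, hi_ppm = 3.28) {
  idx <- ppm_window(diff_spectrum, lo_ppm, hi_ppm)
  x <- diff_spectrum$ppm[idx]
  y <- Re(diff_spectrum$values[idx])
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Edited-area curve across TE
#'
#' Builds the TE-dependence of the edited GABA area from paired ON/OFF series
#' and applies the T2 weight `exp(-TE / t2_ms)`.
#'
#' @param on_series,off_series Lists of `simulated_fid` on a common TE grid
#'   (conditions ON and OFF).
#' @param lb_hz Apodization before integration, Hz (default 6).
#' @param t2_ms In vivo T2 used for the weighted curve, ms (default 88).
#' @param window Integration window, ppm.
#' @param ctx A [spectrometer_context()].
#' @return Object of class `edited_area_curve`: `te_grid`, `area_raw`,
#'   `area_t2`, `t2_ms`.
#' @export
edited_area_curve <- function(on_series, off_series, lb_hz = 6, t2_ms = 88,
                              window = c(2.79, 3.28),
                              ctx = spectrometer_context()) {
  te_on <- vapply(on_series, function(f) f$meta$te, numeric(1))
  te_off <- vapply(off_series, function(f) f$meta$te, numeric(1))
  if (length(te_on) != length(te_off) || any(te_on != te_off)) {
    stop("ON and OFF series are not on the same TE grid")
  }
  area <- mapply(function(on, off) {
    d <- on
    d$samples <- on$samples - off$samples
    d$meta$condition <- "DIFF"
    gaba_edited_area(fid_to_spectrum(d, lb_hz = lb_hz, ctx = ctx),
                     window[1], window[2])
  }, on_series, off_series)
  apply_t2_weight(
    structure(list(te_grid = unname(te_on), area_raw = unname(area),
                   area_t2 = NULL, t2_ms = NULL),
              class = "edited_area_curve"),
    t2_ms
  )
}

#' Apply (or re-apply) T2 weighting to an edited-area curve
#'
#' Sets `area_t2(te) = area_raw(te) * exp(-te / t2_ms)` exactly.
#'
#' @param curve An `edited_area_curve`.
#' @param t2_ms T2 constant, ms; must be positive.
#' @param normalize If `TRUE`, both curves are additionally returned divided
#'   by their own maxima (fields `area_raw_norm`, `area_t2_norm`).
#' @return The updated `edited_area_curve`.
#' @export
apply_t2_weight <- function(curve, t2_ms = 88, normalize = FALSE) {
  stopifnot(inherits(curve, "edited_area_curve"), t2_ms > 0)
  curve$t2_ms <- t2_ms
  curve$area_t2 <- curve$area_raw * exp(-curve$te_grid / t2_ms)
  if (normalize) {
    curve$area_raw_norm <- curve$area_raw / max(curve$area_raw)
    curve$area_t2_norm <- curve$area_t2 / max(curve$area_t2)
  }
  curve
}

#' @export
print.edited_area_curve <- function(x, ...) {
  cat(sprintf(
    "<edited_area_curve> TE %g-%g ms: argmax raw %g ms, argmax T2-weighted (T2 = %g ms) %g ms\n",
    min(x$te_grid), max(x$te_grid),
    x$te_grid[which.max(x$area_raw)], x$t2_ms,
    x$te_grid[which.max(x$area_t2)]))
  invisible(x)
}

#' @export
as.data.frame.edited_area_curve <- function(x, ...) {
  data.frame(te = x$te_grid, area_raw = x$area_raw, area_t2 = x$area_t2)
}

#' Recommended echo time from the overlap and edited-area analyses
#'
#' Reports the TE minimizing the mI overlap, the TE maximizing the T2-weighted
#' edited GABA area, and their intersection. Ties are broken toward the lower
#' TE. If the two optima disagree, `recommended_te` is the overlap optimum and
#' the report flags the disagreement.
#'
#' @param overlap An [build_overlap_curve()] result (must include mI).
#' @param edited An [edited_area_curve()] result.
#' @return Object of class `te_report`.
#' @export
optimal_te_report <- function(overlap, edited) {
  stopifnot(inherits(overlap, "overlap_curve"), inherits(edited, "edited_area_curve"))
  if (!("mI" %in% rownames(overlap$rms))) stop("overlap curve lacks an mI series")
  common <- intersect(overlap$te_grid, edited$te_grid)
  if (!length(common)) stop("overlap and edited-area TE grids are disjoint")
  # which.min/max return the first index, i.e. the lower TE on ties
  te_overlap <- overlap$te_grid[which.min(overlap$rms["mI", ])]
  te_gaba <- edited$te_grid[which.max(edited$area_t2)]
  structure(
    list(optimal_te_overlap = te_overlap,
         optimal_te_gaba_t2 = te_gaba,
         agree = te_overlap == te_gaba,
         recommended_te = te_overlap),
    class = "te_report"
  )
}

#' @export
print.te_report <- function(x, ...) {
  cat(sprintf("<te_report> mI overlap minimum at TE %g ms; T2-weighted GABA maximum at TE %g ms\n",
              x$optimal_te_overlap, x$optimal_te_gaba_t2))
  if (x$agree) {
    cat(sprintf("  recommended TE: %g ms (both analyses agree)\n", x$recommended_te))
  } else {
    cat(sprintf("  recommended TE: %g ms (analyses disagree; overlap minimum used)\n",
                x$recommended_te))
  }
  invisible(x)
}
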