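#' MEGA-PRESS sequence timing
#'
#' Computes pulse-midpoint times for the MEGA-PRESS sequence with the
#' excitation midpoint at time 0: the first refocusing pulse at `te1/2`, the
#' second at `(te + te1)/2`, acquisition starting at `te`, the first editing
#' pulse symmetrically between excitation and the second refocusing pulse, and
#' the second editing pulse halfway between the second refocusing pulse and the
#' start of acquisition. The two editing pulses are therefore always separated
#' by exactly `te/2`, which is what makes the editing refocus J-evolution of
#' the targeted coupling.
#'
#' @param te Echo time, ms.
#' @param te1 First PRESS sub-echo time, ms (default 16; the vendor split is
#'   rarely published, so this is exposed).
#' @param edit_ms Editing pulse duration, ms (default 15).
#' @param refoc_ms Refocusing pulse duration, ms (0 for ideal pulses).
#' @return Object of class `sequence_timing` with midpoints `t_refoc1`,
#'   `t_refoc2`, `t_edit1`, `t_edit2`, `t_acq` (ms) and the durations.
#' @export
#' @examples
#' compute_timing(64, 16)
compute_timing <- function(te, te1 = 16, edit_ms = 15, refoc_ms = 0) {
  stopifnot(is.numeric(te), is.numeric(te1))
  if (!(te1 > 0) || !(te1 < te)) {
    stop("te1 must satisfy 0 < te1 < te (got te1 = ", te1, ", te = ", te, ")")
  }
  t_refoc1 <- te1 / 2
  t_refoc2 <- (te + te1) / 2
  t_edit1 <- t_refoc2 / 2
  t_edit2 <- (t_refoc2 + te) / 2
  tm <- structure(
    list(te = te, te1 = te1,
         t_refoc1 = t_refoc1, t_refoc2 = t_refoc2,
         t_edit1 = t_edit1, t_edit2 = t_edit2, t_acq = te,
         edit_ms = edit_ms, refoc_ms = refoc_ms),
    class = "sequence_timing"
  )
  iv <- timing_intervals(tm)
  for (k in seq_len(nrow(iv) - 1)) {
    if (iv$start[k + 1] < iv$end[k] - 1e-9) {
      stop("pulse intervals overlap: ", iv$label[k], " and ", iv$label[k + 1],
           " (TE ", te, " ms, te1 ", te1, " ms)")
    }
  }
  tm
}

timing_intervals <- function(tm) {
  data.frame(
    label = c("excitation", "refoc1", "edit1", "refoc2", "edit2", "acquisition"),
    start = c(0,
              tm$t_refoc1 - tm$refoc_ms / 2,
              tm$t_edit1 - tm$edit_ms / 2,
              tm$t_refoc2 - tm$refoc_ms / 2,
              tm$t_edit2 - tm$edit_ms / 2,
              tm$t_acq),
    end = c(0,
            tm$t_refoc1 + tm$refoc_ms / 2,
            tm$t_edit1 + tm$edit_ms / 2,
            tm$t_refoc2 + tm$refoc_ms / 2,
            tm$t_edit2 + tm$edit_ms / 2,
            tm$t_acq)
  )
}

#' @export
print.sequence_timing <- function(x, ...) {
  cat(sprintf(
    "<sequence_timing> TE %.4g ms (te1 %.4g): refoc %.4g / %.4g, edit %.4g / %.4g, acq %.4g\n",
    x$te, x$te1, x$t_refoc1, x$t_refoc2, x$t_edit1, x$t_edit2, x$t_acq))
  invisible(x)
}

#' Spatial simulation grid
#'
#' The simulated plane spans the two refocusing-gradient axes; the excitation
#' axis is treated as ideal. The plane extends beyond the nominal voxel to
#' capture the transition bands of the refocusing pulses.
#'
#' @param extent_mm Edge length of the simulated plane, mm (default 36).
#' @param n_segments Segments per axis, must be odd so a centre point exists
#'   (default 19).
#' @param nominal_voxel_mm Nominal voxel edge, mm (default 30).
#' @return Object of class `sim_grid`.
#' @export
sim_grid <- function(extent_mm = 36, n_segments = 19, nominal_voxel_mm = 30) {
  stopifnot(extent_mm >= nominal_voxel_mm, n_segments >= 1)
  if (n_segments %% 2 == 0) stop("n_segments must be odd (centre point required)")
  structure(
    list(extent_mm = extent_mm, n_segments = n_segments,
         nominal_voxel_mm = nominal_voxel_mm,
         positions_mm = if (n_segments == 1) 0 else
           seq(-extent_mm / 2, extent_mm / 2, length.out = n_segments)),
    class = "sim_grid"
  )
}

#' Editing condition
#'
#' @param label `"ON"` (editing pulse on the coupled partner, 1.9 ppm for
#'   GABA), `"OFF"` (symmetric non-interacting frequency, 7.5 ppm) or
#'   `"NONE"` (editing pulses replaced by free evolution; plain PRESS timing).
#' @param carrier_ppm Optional override of the editing-pulse carrier.
#' @return Object of class `edit_condition`.
#' @export
edit_condition <- function(label = c("OFF", "ON", "NONE"), carrier_ppm = NULL) {
  label <- match.arg(label)
  if (is.null(carrier_ppm)) {
    carrier_ppm <- switch(label, ON = 1.9, OFF = 7.5, NONE = NA_real_)
  }
  structure(list(label = label, carrier_ppm = carrier_ppm),
            class = "edit_condition")
}

# Precompute everything that does not depend on TE: operators, free
# Hamiltonian and its eigensystem, editing-pulse propagator, and (in
# shaped-refocus mode) the per-position refocusing propagators.
megapress_setup <- function(system, condition, grid = sim_grid(),
                            mode = c("shaped-refocus", "ideal-localized"),
                            edit_pulse = make_sinc_gaussian(),
                            refoc_pulse = make_refocusing_pulse(),
                            ctx = spectrometer_context()) {
  mode <- match.arg(mode)
  stopifnot(inherits(system, "spin_system"), inherits(condition, "edit_condition"))
  ops <- spin_operators(system$n_protons)
  H <- build_hamiltonian(system, ctx)
  eig <- herm_eigen(H)
  U_edit <- NULL
  if (condition$label != "NONE") {
    off_edit <- ppm_to_offset_hz(condition$carrier_ppm, ctx)
    U_edit <- pulse_propagator(edit_pulse, H, ops, off_edit)
  }
  refoc <- NULL
  if (mode == "shaped-refocus") {
    g_hz_mm <- refoc_pulse$bandwidth_hz / grid$nominal_voxel_mm
    refoc <- lapply(grid$positions_mm, function(x) {
      pulse_propagator(refoc_pulse, H, ops, g_hz_mm * x, frame = FALSE)
    })
  }
  U90 <- propagator(ops$Fx, pi / 2, herm_eigen(ops$Fx))
  U180y <- propagator(ops$Fy, pi, herm_eigen(ops$Fy))
  list(system = system, condition = condition, grid = grid, mode = mode,
       edit_pulse = edit_pulse, refoc_pulse = refoc_pulse, ctx = ctx,
       ops = ops, H = H, eig = eig, U_edit = U_edit, refoc = refoc,
       U90 = U90, U180y = U180y)
}

# Apply a refocusing event: shaped per-position conjugation + coherence
# projection, averaged across the grid axis; or an exact 180y in ideal mode.
apply_refocusing <- function(rho, setup, p_after) {
  ops <- setup$ops
  if (setup$mode == "ideal-localized") {
    rho <- conj_by(setup$U180y, rho)
    return(project_coherence(rho, ops$m, p_after))
  }
  acc <- matrix(0i, nrow(rho), ncol(rho))
  for (U in setup$refoc) {
    acc <- acc + project_coherence(conj_by(U, rho), ops$m, p_after)
  }
  acc / length(setup$refoc)
}

apply_editing <- function(rho, setup, p_keep, pulse_ms) {
  if (is.null(setup$U_edit)) {
    return(evolve(rho, setup$eig, pulse_ms / 1000))
  }
  rho <- conj_by(setup$U_edit, rho)
  project_coherence(rho, setup$ops$m, p_keep)
}

# Propagate one TE through the sequence and acquire the FID.
run_megapress <- function(setup, timing, n_points = 2048, sw_hz = 2000) {
  ops <- setup$ops
  iv <- timing_intervals(timing)
  gaps <- (iv$start[-1] - iv$end[-nrow(iv)]) / 1000  # s
  if (any(gaps < -1e-12)) stop("invalid timing for the configured pulse durations")
  rho <- conj_by(setup$U90, ops$Fz)
  rho <- project_coherence(rho, ops$m, -1)
  rho <- evolve(rho, setup$eig, gaps[1])
  rho <- apply_refocusing(rho, setup, p_after = +1)
  rho <- evolve(rho, setup$eig, gaps[2])
  rho <- apply_editing(rho, setup, p_keep = +1, pulse_ms = timing$edit_ms)
  rho <- evolve(rho, setup$eig, gaps[3])
  rho <- apply_refocusing(rho, setup, p_after = -1)
  rho <- evolve(rho, setup$eig, gaps[4])
  rho <- apply_editing(rho, setup, p_keep = -1, pulse_ms = timing$edit_ms)
  rho <- evolve(rho, setup$eig, gaps[5])
  drift <- abs(sum(Re(diag(rho))))  # selected coherences carry zero trace
  samples <- acquire_fid(rho, setup$eig, ops, n_points, 1 / sw_hz)
  n <- setup$system$n_protons
  samples <- samples * 1i * 2^(2 - n) * setup$system$scale
  structure(
    list(samples = samples, dwell = 1 / sw_hz, n_points = n_points,
         meta = list(system = setup$system$name,
                     metabolite = setup$system$metabolite,
                     te = timing$te, te1 = timing$te1,
                     condition = setup$condition$label,
                     mode = setup$mode,
                     grid = if (setup$mode == "shaped-refocus")
                       setup$grid$n_segments else 1L,
                     lb_hz = 0, trace_drift = drift)),
    class = "simulated_fid"
  )
}

# Fast acquisition: express rho and F+ in the Hamiltonian eigenbasis; the FID
# is then a finite sum of complex exponentials at the eigenvalue differences.
acquire_fid <- function(rho, eig, ops, n_points, dwell_s) {
  V <- eig$vectors
  rho_e <- Conj(t(V)) %*% rho %*% V
  Fp_e <- Conj(t(V)) %*% ops$Fp %*% V
  A <- t(Fp_e) * rho_e
  omega <- outer(eig$values, eig$values, `-`)
  keep <- Mod(A) > max(Mod(A), 1e-300) * 1e-12
  amps <- A[keep]
  w <- omega[keep]
  tvec <- (seq_len(n_points) - 1) * dwell_s
  out <- complex(n_points)
  block <- 256L
  for (s in seq(1, n_points, by = block)) {
    idx <- s:min(s + block - 1L, n_points)
    out[idx] <- as.vector(crossprod(exp(-1i * (w %o% tvec[idx])), amps))
  }
  out
}

#' @export
print.simulated_fid <- function(x, ...) {
  cat(sprintf("<simulated_fid> %s [%s] TE %.4g ms: %d pts, sw %.4g Hz, mode %s\n",
              x$meta$system, x$meta$condition, x$meta$te, x$n_points,
              1 / x$dwell, x$meta$mode))
  invisible(x)
}

#' Simulate a MEGA-PRESS FID for one spin system
#'
#' Propagates the spin system through excitation (ideal 90 degrees), two
#' refocusing pulses (exact rotations in `ideal-localized` mode, shaped pulses
#' under a slice gradient averaged over the spatial grid in `shaped-refocus`
#' mode), and two frequency-selective shaped editing pulses, with
#' coherence-order projection after every pulse so that only the
#' doubly-refocused pathway survives (the infinite-crusher limit). Relaxation
#' is not simulated. The signal is normalized per proton so that integrals
#' scale linearly with concentration and proton count.
#'
#' @param system A [spin_system()].
#' @param timing A [compute_timing()] result (its `refoc_ms` is overridden to
#'   match the refocusing pulse in shaped mode).
#' @param condition An [edit_condition()].
#' @param grid A [sim_grid()]; used in `shaped-refocus` mode.
#' @param edit_pulse Editing [rf_pulse()]; default 15 ms / 82 Hz sinc-Gaussian.
#' @param refoc_pulse Refocusing [rf_pulse()] for shaped mode.
#' @param mode `"shaped-refocus"` (default) or `"ideal-localized"`.
#' @param ctx A [spectrometer_context()].
#' @param n_points Acquired complex points (default 2048).
#' @param sw_hz Spectral width in Hz (default 2000).
#' @return A `simulated_fid` object.
#' @export
simulate_fid <- function(system, timing, condition, grid = sim_grid(),
                         edit_pulse = make_sinc_gaussian(),
                         refoc_pulse = make_refocusing_pulse(),
                         mode = c("shaped-refocus", "ideal-localized"),
                         ctx = spectrometer_context(),
                         n_points = 2048, sw_hz = 2000) {
  mode <- match.arg(mode)
  setup <- megapress_setup(system, condition, grid, mode, edit_pulse,
                           refoc_pulse, ctx)
  timing <- compute_timing(timing$te, timing$te1,
                           edit_ms = if (condition$label == "NONE") 0 else
                             edit_pulse$duration_ms,
                           refoc_ms = if (mode == "shaped-refocus")
                             refoc_pulse$duration_ms else 0)
  run_megapress(setup, timing, n_points, sw_hz)
}

#' Simulate a series of echo times
#'
#' Runs [simulate_fid()] over an ascending TE grid with shared settings,
#' reusing the pulse propagators across TEs (they do not depend on TE).
#'
#' @inheritParams simulate_fid
#' @param te_grid Ascending numeric vector of echo times, ms.
#' @param te1 First sub-echo time passed to [compute_timing()].
#' @return Named list of `simulated_fid`, names `"te<ms>"`.
#' @export
#' @examples
#' sys <- load_spin_systems()
#' fids <- simulate_te_series(sys$Gly, c(64, 68), edit_condition("OFF"),
#'                            mode = "ideal-localized")
simulate_te_series <- function(system, te_grid, condition, te1 = 16,
                               grid = sim_grid(),
                               edit_pulse = make_sinc_gaussian(),
                               refoc_pulse = make_refocusing_pulse(),
                               mode = c("shaped-refocus", "ideal-localized"),
                               ctx = spectrometer_context(),
                               n_points = 2048, sw_hz = 2000) {
  mode <- match.arg(mode)
  if (!length(te_grid) || is.unsorted(te_grid, strictly = TRUE)) {
    stop("te_grid must be non-empty and strictly ascending")
  }
  setup <- megapress_setup(system, condition, grid, mode, edit_pulse,
                           refoc_pulse, ctx)
  refoc_ms <- if (mode == "shaped-refocus") refoc_pulse$duration_ms else 0
  edit_ms <- if (condition$label == "NONE") 0 else edit_pulse$duration_ms
  out <- lapply(te_grid, function(te) {
    tm <- compute_timing(te, te1, edit_ms = edit_ms, refoc_ms = refoc_ms)
    run_megapress(setup, tm, n_points, sw_hz)
  })
  names(out) <- paste0("te", te_grid)
  out
}

#' Simulate the summed FID of a multi-fragment metabolite
#'
#' Metabolites shipped as several uncoupled fragments (Glc anomers, Cr and NAA
#' groups) are simulated fragment by fragment and summed with their `scale`
#' weights (signals add linearly).
#'
#' @param systems Named list of [spin_system()] (see [load_spin_systems()]).
#' @param metabolite Metabolite name.
#' @param te_grid Echo times, ms.
#' @param condition An [edit_condition()].
#' @param ... Passed to [simulate_te_series()].
#' @return Named list of `simulated_fid` (one per TE); `meta$system` is the
#'   metabolite name.
#' @export
simulate_metabolite_series <- function(systems, metabolite, te_grid, condition,
                                       ...) {
  grp <- metabolite_groups(systems)[[metabolite]]
  if (is.null(grp)) stop("unknown metabolite: ", metabolite)
  per_frag <- lapply(grp, simulate_te_series, te_grid = te_grid,
                     condition = condition, ...)
  out <- per_frag[[1]]
  if (length(per_frag) > 1) {
    for (f in per_frag[-1]) {
      for (k in seq_along(out)) out[[k]]$samples <- out[[k]]$samples + f[[k]]$samples
    }
  }
  for (k in seq_along(out)) {
    out[[k]]$meta$system <- metabolite
    out[[k]]$meta$metabolite <- metabolite
  }
  out
}
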