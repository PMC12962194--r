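# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is generated in code; the heavier simulations are reused across
# test files through these accessors.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_ctx <- function() fx("ctx", function() spectrometer_context())

fx_systems <- function() fx("systems", function() load_spin_systems())

fx_edit_pulse <- function() {
  fx("edit_pulse", function() make_sinc_gaussian(15, 82, n_steps = 128))
}

# weakly coupled two-spin test system (delta >> J)
fx_ax_pair <- function() {
  fx("ax_pair", function() {
    spin_system("AX", shifts = c(1.0, 8.0), couplings = list(c(1, 2, 7)))
  })
}

# unit-response library on the cohort grid (both TEs, ON and OFF)
fx_unit_lib <- function() {
  fx("unit_lib", function() {
    cohort_unit_library(fx_systems(), cohort_config())
  })
}

fx_cohort <- function() {
  fx("cohort", function() {
    generate_cohort(6, cohort_config(), master_seed = 424242,
                    systems = fx_systems(), unit_lib = fx_unit_lib())
  })
}

fx_basis64_off <- function() {
  fx("basis64_off", function() cohort_basis(fx_cohort(), 64, "OFF"))
}

# acceptance-scale simulations (shaped-refocus, reduced 9x9 grid)
fx_grid9 <- function() fx("grid9", function() sim_grid(36, 9, 30))

fx_series_shaped <- function(metabolite, te_grid = seq(60, 88, 2)) {
  fx(paste0("shaped_", metabolite), function() {
    simulate_metabolite_series(
      fx_systems(), metabolite, te_grid, edit_condition("OFF"), te1 = 16,
      grid = fx_grid9(), edit_pulse = fx_edit_pulse(),
      mode = "shaped-refocus")
  })
}

fx_gaba_edited <- function() {
  fx("gaba_edited", function() {
    tes <- seq(60, 80, 2)
    list(
      on = simulate_metabolite_series(fx_systems(), "GABA", tes,
                                      edit_condition("ON"), te1 = 16,
                                      edit_pulse = fx_edit_pulse(),
                                      mode = "ideal-localized"),
      off = simulate_metabolite_series(fx_systems(), "GABA", tes,
                                       edit_condition("OFF"), te1 = 16,
                                       edit_pulse = fx_edit_pulse(),
                                       mode = "ideal-localized"))
  })
}

# small synthetic Lorentzian FID: exp(-pi * w * t) * exp(2i pi f t)
lorentz_fid <- function(w_hz, f_hz, n = 2048, sw = 2000, amp = 1) {
  tvec <- (seq_len(n) - 1) / sw
  structure(
    list(samples = amp * exp(-pi * w_hz * tvec) * exp(2i * pi * f_hz * tvec),
         dwell = 1 / sw, n_points = n,
         meta = list(system = "synthetic", condition = "OFF", lb_hz = 0)),
    class = "simulated_fid")
}
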