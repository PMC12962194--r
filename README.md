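# glymega

Echo-time optimization for simultaneous glycine and GABA detection with
MEGA-PRESS at 3 T, as a reproducible density-matrix simulation and analysis
pipeline in R.

## The problem

Glycine (Gly, ~0.7 mM in brain) appears as a singlet at 3.55 ppm buried under
the myo-inositol (mI, 4–8 mM) multiplet, whose 3.61 ppm resonance is coupled
to its 3.52 ppm resonance with J ≈ 10 Hz. Because the Gly singlet does not
evolve with echo time while the strongly coupled mI multiplet does, the echo
time (TE) of a MEGA-PRESS acquisition can be chosen so that mI contributes
minimal signal to the 3.5–3.6 ppm window — without sacrificing the 3.0 ppm
edited GABA signal, which tolerates a broad TE range. That makes it possible
to quantify both inhibitory neurotransmitters from one scan: GABA from the
edit-ON − edit-OFF difference, Gly from the edit-OFF or SUM spectrum.

`glymega` provides:

* a density-matrix simulator for spin systems under the full strong-coupling
  Hamiltonian `H = Σ 2π ν_i I_iz + Σ 2π J_ij (I_i · I_j)`, propagated through
  the MEGA-PRESS sequence (ideal excitation, shaped or ideal refocusing
  pulses over a spatial grid, shaped sinc-Gaussian editing pulses,
  coherence-order selection);
* spectral processing: exponential apodization, zero-filling, SNR/FWHM
  measures, calibrated noise injection and linewidth matching;
* the TE-optimization metrics: RMS of nuisance metabolites (mI, Glc, Thr) in
  the 3.5–3.6 ppm Gly window across TE, and the edited GABA area
  (2.79–3.28 ppm) across TE with and without `exp(−TE/88 ms)` T2 weighting;
* a linear-combination fitter (non-negative least squares plus polynomial
  baseline) with Cramér–Rao lower bounds, a Gly-inclusion/exclusion
  comparison, and a Gaussian fitter for the edited 3.0 ppm peak;
* a synthetic six-subject cohort generator (edit-ON/OFF pairs at TE 64 and
  68 ms, concentrations, linewidths and SNR drawn around realistic in vivo
  values) with the cohort statistics: between-acquisition and inter-subject
  coefficients of variation and exact Mann–Whitney U tests.

## Worked example

```r
library(glymega)
systems <- load_spin_systems()          # shipped shift/J tables (YAML)

pulse <- make_sinc_gaussian()           # 15 ms editing pulse, 82 Hz target
pulse
inversion_fwhm(pulse)

compute_timing(64, 16)                  # MEGA-PRESS timing at TE 64 ms

on  <- simulate_metabolite_series(systems, "GABA", seq(60, 80, 4),
                                  edit_condition("ON"), mode = "ideal-localized")
off <- simulate_metabolite_series(systems, "GABA", seq(60, 80, 4),
                                  edit_condition("OFF"), mode = "ideal-localized")
edited_area_curve(on, off)

cohort <- generate_cohort(n_subjects = 6, master_seed = 1, systems = systems)
cohort_report(cohort)
```

prints

```
<rf_pulse> sinc-gaussian: 15 ms, 128 steps, flip 180.0 deg, bandwidth 82 Hz
[1] 82
<sequence_timing> TE 64 ms (te1 16): refoc 8 / 40, edit 20 / 52, acq 64
<edited_area_curve> TE 60-80 ms: argmax raw 68 ms, argmax T2-weighted (T2 = 88 ms) 64 ms
<cohort_report>
 te inter_subject_cv_off inter_subject_cv_sum mean_between_acq_cv_gly
 64                 11.5                 10.3                    1.34
 68                 10.5                 10.1                    1.99
 mean_gly_crlb_off mean_gly_crlb_sum mean_gaba_area mean_gaba_fit_err
              2.35              1.65           23.0              20.5
              2.55              1.77           25.7              20.4
rank-sum p (between-acquisition Gly CV, TE 64 vs 68): 0.3939
rank-sum p (GABA+ area): 0.1797
```

Reading this: the editing pulse calibrates to exactly its 82 Hz inversion
bandwidth; the sequence timing places the two editing pulses 32 ms apart
(TE/2); the T2-weighted edited GABA area peaks at TE 64 ms while the raw
area is a plateau (its argmax on this coarse 4 ms grid is 68 ms; on the full
2 ms grid it is 66 ms); and in the synthetic cohort the Gly estimates have
lower CRLBs at TE 64 ms than at TE 68 ms, equal GABA areas at both TEs
(rank-sum p = 0.18), and a between-acquisition CV of 1–2% — far tighter than
in vivo values because the cohort is fit with the exact basis that generated
it (see the methods vignette for what the generator does and does not
emulate).

The full pipeline — overlap curves on the spatial grid, edited-area curves,
cohort, fits and summary tables, with a checksum manifest — runs as

```r
run_pipeline(run_config(seed = 1), outdir = "run1")
```

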