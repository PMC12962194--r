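---
title: "Methods: echo-time optimization for simultaneous glycine and GABA detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: echo-time optimization for simultaneous glycine and GABA detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Glycine (Gly) is an inhibitory neurotransmitter present in brain at roughly
0.7 mM. Its two equivalent, uncoupled protons give a singlet at 3.55 ppm that
sits directly under the much larger myo-inositol (mI) multiplet: mI is 4-8 mM
in healthy brain, and its 3.61 ppm resonance is coupled to its 3.52 ppm
resonance with J of about 10 Hz. Because the Gly singlet does not evolve with
echo time while the strongly coupled mI multiplet does, there can exist echo
times at which mI contributes little signal to the 3.5-3.6 ppm window while
Gly is untouched. GABA, the other inhibitory neurotransmitter, is detected at
3 T by J-difference editing (MEGA-PRESS): a frequency-selective pulse applied
at 1.9 ppm in half of the transients refocuses the J-evolution of the 3.0 ppm
GABA resonance, so the ON - OFF difference isolates it. GABA editing works
over a broad TE range, which leaves room to pick the TE inside that range
that also minimizes the mI contamination of the Gly window. glymega
implements the simulation and analysis machinery to make that choice and to
study how reliably Gly can then be quantified from the edit-OFF and SUM
(ON + OFF) spectra of a single MEGA-PRESS acquisition.

## Density-matrix engine

Each metabolite is a set of spin-1/2 nuclei with chemical shifts
$\delta_i$ (ppm) and scalar couplings $J_{ij}$ (Hz), evolving under the full
strong-coupling rotating-frame Hamiltonian

$$H = \sum_i 2\pi\,\nu_i I_{iz} + \sum_{i<j} 2\pi J_{ij}\,
      \mathbf{I}_i\cdot\mathbf{I}_j,
  \qquad \nu_i = (\delta_{\mathrm{centre}} - \delta_i)\, f_0,$$

with $f_0 = 127.73$ MHz at 3 T and the carrier at 4.65 ppm (water). The
strong-coupling ($\mathbf{I}\cdot\mathbf{I}$) form matters: at 3 T the mI
ring protons are separated by about the size of their couplings, and the TE
structure of the 3.5-3.6 ppm window is a strong-coupling effect. Equivalent
spins are simulated explicitly; metabolites whose protons split into
uncoupled fragments (creatine CH3/CH2, the NAA acetyl group, the two glucose
anomers) are shipped as separate small systems whose signals add with fixed
weights, which keeps the largest Hilbert space at $2^7$.

The MEGA-PRESS sequence is propagated as: ideal 90° excitation; two
refocusing pulses at $t_{E1}/2$ and $(TE + t_{E1})/2$; two shaped editing
pulses, the first symmetric between excitation and the second refocusing
pulse, the second halfway between that pulse and acquisition (their
separation is therefore exactly $TE/2$); acquisition starting at $TE$
(2000 Hz, 2048 complex points). Shift and J evolution during the 15 ms
editing pulses is included in the piecewise-constant pulse propagators.

Coherence selection is implemented as coherence-order projection: after every
pulse the density matrix is projected onto the coherence order of the
doubly-refocused pathway ($-1 \to +1 \to -1$, with editing pulses
order-preserving). This is the infinite-crusher limit of the gradient scheme
used on scanners. We deliberately did not implement selection by cycling the
refocusing-pulse phase between $\pm x$: for any 180°-class pulse the $+x$ and
$-x$ propagators differ only by a global phase and act identically on the
density matrix, so such a cycle selects nothing. The projection is exact,
deterministic, and (for ideal refocusing pulses) provably equivalent to a
simulation without any selection, which we verified against brute-force
propagation to 1e-13.

Acquisition uses the eigenbasis of the free Hamiltonian: the FID is a finite
sum of complex exponentials at eigenvalue differences, evaluated in blocks.
Signals are normalized per proton, so FIDs are linear in concentration and
proton count, and mixtures are exact weighted sums of unit responses.
Relaxation is not simulated; T2 enters only as the post-hoc area weight
$\exp(-TE/T_2)$ with $T_2 = 88$ ms for the edited GABA analysis.

## Pulses

The editing pulse is a single-lobe sinc under a Gaussian envelope, 15 ms
long. Only duration and bandwidth are physically pinned down, so the Gaussian
width is calibrated numerically (1-D root finding on a single-spin Bloch
simulation) until the inversion profile's FWHM equals the requested 82 Hz;
the B1 scale is set for an exact on-resonance 180°. The calibration knob
spans roughly 60-110 Hz at 15 ms; both the truncation ratio and the step
count (default 128) are exposed.

The refocusing pulse in `shaped-refocus` mode is a Hamming-apodized
amplitude-modulated sinc, 6 ms with a time-bandwidth product of 8 (about
1.3 kHz bandwidth), played under a gradient scaled so its bandwidth covers
the 30 mm nominal voxel; the simulated plane is 36 mm to capture the
transition bands, split into 19 x 19 segments (9 x 9 in desk-scale
analyses). We initially used a much lower time-bandwidth product (4.2), but
its in-plane refocusing efficiency is only about 50% and transition-band
behaviour then dominates the nuisance-metabolite TE curves, pushing the mI
minimum out of the 60-88 ms window entirely. A 1.3 kHz profile is typical of
3 T PRESS refocusing pulses and restores the expected interior minimum; the
time-bandwidth product remains configurable and results in the 3.5-3.6 ppm
window should be read with this sensitivity in mind. The frame-return factor
of a gradient-driven pulse is dropped from its propagator, which emulates the
slice-refocusing/crusher lobes that rewind the gradient-induced linear phase
for the selected pathway.

The PRESS sub-echo split is not standardized on scanners; we default to
$t_{E1} = 16$ ms. With 15 ms editing pulses and 6 ms refocusing pulses the
sequence fits together for $t_{E1}$ of roughly 12-18 ms at TE 60. Within that
range the mI-minimum TE moves by one grid step (64 ms at 14-16 ms, 66 ms at
18 ms), which we treat as the intrinsic uncertainty of the analysis.

## The two analyses and their simulation modes

The nuisance-overlap analysis simulates Gly, mI, Glc and Thr edit-OFF over
TE 60-88 ms (2 ms steps), applies 3 Hz exponential apodization, and computes
the RMS of the real spectrum in 3.5-3.6 ppm per TE, scaled to nominal
concentrations (Gly 0.7, mI 6.0, Glc 1.16, Thr 0.33 mM; the mI value is a
free parameter inside the healthy 4-8 mM range and the normalized overlap is
roughly proportional to it). Curves are reported normalized to the Gly RMS at
the same TE. This analysis runs in `shaped-refocus` mode: the TE structure of
strongly coupled spins depends measurably on the refocusing profile and its
transition bands, and an ideal-pulse simulation gives qualitatively different
curves (monotone in TE rather than dipping at 64 ms).

The edited-GABA analysis simulates ON (1.9 ppm) and OFF (7.5 ppm) at
TE 60-80 ms, applies 6 Hz apodization, and integrates the real difference
spectrum over 2.79-3.28 ppm, with and without the $\exp(-TE/88\,\mathrm{ms})$
weight. This analysis runs in `ideal-localized` mode: its TE dependence is
editing-pulse J-refocusing physics, not localization physics, and our
synthetic refocusing pulse (a stand-in for unpublished vendor pulses) adds
transition-band modulation that obscures the plateau. Under ideal
localization the edited area is flat to within 10% across 60-80 ms with a raw
maximum at 66 ms, moving to 64 ms once T2 weighting is applied.

`optimal_te_report()` combines the two: the TE minimizing the mI overlap, the
TE maximizing the T2-weighted edited area, their agreement, and a
recommendation; ties break toward the lower TE.

## Spectral processing conventions

Exponential apodization is $\exp(-\pi\,\mathrm{lb}\,t)$, so `lb_hz` is
exactly the Lorentzian FWHM added to every line. The ppm axis is
$\delta_{\mathrm{centre}} - f/f_0$, descending left to right. SNR is the
creatine peak maximum divided by the SD of the real part in 10-12 ppm; FWHM
is measured on the 2.0 ppm NAA peak with linear interpolation at half
maximum. Simulated spectra come out of the engine phased (the global
convention makes an uncoupled singlet positive absorption at every TE), so
RMS and fit operations use the real part without per-spectrum rephasing;
zero-order phasing utilities (analytic first-point, and a search maximizing
the 2.8-3.2 ppm integral for noisy data) are provided but are no-ops on
clean simulations. The overlap pipeline uses no zero-filling; the fitting
pipeline zero-fills to 4096.

Noise is complex white Gaussian added in the time domain, with
$\sigma_t = \mathrm{peak}_{\mathrm{Cr}}/(\mathrm{SNR}\sqrt{N})$ so the
measured SNR lands on the target; the same seed gives bit-identical noise.
Linewidth matching applies the width difference as extra apodization with a
fixed-point correction (0.5% tolerance, at most three iterations).

## Linear-combination fitting and CRLBs

`fit_lcm()` fits the real spectrum over 0.2-4.2 ppm as a non-negative
combination of unit-concentration simulated basis responses plus an
unconstrained polynomial baseline (default order 4). The baseline is profiled
out exactly by projection, so the returned amplitudes solve the joint
problem; a ridge penalty of 1e-6 times the mean squared basis norm keeps
near-collinear pairs finite instead of excluding them. The basis is
lineshape-matched to the data by broadening every response until the basis
creatine FWHM equals the data NAA FWHM (a single-lineshape simplification;
no per-metabolite shifts or lineshape parameters). Cramer-Rao bounds come
from the Fisher information of the full design (basis plus baseline columns)
with the noise variance estimated from 10-12 ppm:
$\mathrm{CRLB}_i = 100\sqrt{(F^{-1})_{ii}}/c_i$ percent, reported as missing
for non-positive estimates. Threonine estimates with CRLB above 40% are
masked from cohort summaries (its single 3-4 ppm proton at 0.33 mM fits
poorly). The 3.0 ppm edited peak in difference spectra is fit by nonlinear
least squares as a single Gaussian plus linear baseline over 2.79-3.55 ppm;
the area is the analytic $a\,\sigma\sqrt{2\pi}$ and the fit error is
$100\,\mathrm{SD}(\mathrm{residual})/a$.

## The synthetic cohort

`generate_cohort()` emulates a six-subject study acquiring edit-ON/OFF pairs
at TE 64 and 68 ms: per-subject concentrations are truncated-normal draws
centred on edit-OFF TE 64 estimates typical of occipital voxels (Gly
0.88 ± 0.18, mI 3.34 ± 0.74, Glc 1.73 ± 0.27 mM; Thr, GABA, Cr and NAA at
nominal values with ~10% spread), per-subject NAA linewidths are
4.73 ± 0.57 Hz truncated to 3.5-7 Hz, and independent noise brings the
edit-OFF SNR to 247 (SUM spectra then gain the theoretical $\sqrt{2}$).
Everything derives from one master seed. The unit-response library is built
in `ideal-localized` mode: the cohort exercises the estimation pipeline, not
localization. `cohort_report()` then runs the full downstream analysis:
linewidth-matched OFF and SUM fits, Gaussian DIFF fits, between-acquisition
CV ($100\,|c_{OFF}-c_{SUM}|/\bar c$), inter-subject CV ($100\,s/\bar c$,
sample SD), the Gly-included/Gly-excluded paired comparison, and two-sided
Mann-Whitney U tests between TEs (exact enumeration of the permutation
distribution up to 2e5 arrangements, normal approximation with tie
correction beyond).

What the generator does not emulate — and hence what passing tests do not
show about real data: macromolecule signal (in vivo "GABA+" includes
co-edited macromolecules; our edited peak is pure GABA and, at 5 Hz
linewidth, a resolved pseudo-doublet, so single-Gaussian fit errors are
~20% rather than the ~5% seen in vivo), frequency drift and motion, water
residual and baseline distortion, and any mismatch between the data and the
fitting basis (the cohort is fit with the basis that generated it). That
last point matters for interpretation: in vivo, Gly estimates at TE 68 are
destabilized by the larger mI overlap interacting with model mismatch; in
our matched-basis cohort the TE 68 penalty survives only as a consistently
higher Gly CRLB, while the between-acquisition CV advantage of TE 64 appears
in only ~60-70% of cohort replicates.

## Numerical choices and limitations

Hamiltonian eigendecompositions use LAPACK's Hermitian solvers; propagator
unitarity and density-matrix trace are preserved at the 1e-10 level. The
acquisition sum drops transition amplitudes below 1e-12 of the maximum.
Desk-scale analyses use the 9 x 9 grid, 128-step editing pulses and 64-step
refocusing pulses; the full 19 x 19 grid gives the same optima. The argmin/
argmax reports break ties toward the lower TE.

Two results are sensitive to parameters that are not standardized: the
glucose 3.5-3.6 ppm RMS curve is nearly flat after its initial drop and its
global minimum moves between ~62 ms (ideal localization) and the top of the
TE range (shaped mode) depending on the refocusing profile; and the absolute
normalized Gly-mI overlap at our defaults evaluates to roughly 110% at TE 64
and 125% at TE 68 (ratio ~1.13), varying severalfold with the refocusing
profile, the sub-echo split and the assumed mI concentration. The location
of the mI minimum at 64 ms and the edited-GABA optima are robust to these
choices; the absolute overlap level and its 64-to-68 ms growth factor are
not, and should be treated as configuration-dependent.
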