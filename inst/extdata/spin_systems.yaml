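# Proton spin-system parameters (chemical shifts in ppm, scalar couplings in Hz)
# for the metabolites simulated by glymega. These are editable configuration
# values transcribed from the standard literature compilation of metabolite
# shifts and couplings (Govindaraju, Young & Maudsley, NMR Biomed 2000, and
# common usage in MRS simulation toolkits); they are NOT code. Uncoupled
# fragments of a metabolite are listed as separate small systems sharing a
# `metabolite` label, with `scale` giving the fragment weight (proton
# multiplicity of a collapsed equivalent group, or anomeric fraction).
#
# reference_concentration_mM is the nominal healthy-brain concentration used
# for in vivo scaling of simulated responses.

- name: Gly
  shifts: [3.548, 3.548]
  couplings: []
  reference_concentration_mM: 0.7

- name: mI
  shifts: [3.5217, 4.0538, 3.5217, 3.6144, 3.2690, 3.6144]
  couplings:
    - [1, 2, 2.889]
    - [1, 6, 9.998]
    - [2, 3, 3.006]
    - [3, 4, 9.997]
    - [4, 5, 9.485]
    - [5, 6, 9.482]
  reference_concentration_mM: 6.0

- name: Glc_alpha
  metabolite: Glc
  scale: 0.36
  shifts: [5.216, 3.519, 3.698, 3.395, 3.822, 3.826, 3.749]
  couplings:
    - [1, 2, 3.8]
    - [2, 3, 9.6]
    - [3, 4, 9.4]
    - [4, 5, 9.9]
    - [5, 6, 1.5]
    - [5, 7, 6.0]
    - [6, 7, -12.1]
  reference_concentration_mM: 1.16

- name: Glc_beta
  metabolite: Glc
  scale: 0.64
  shifts: [4.630, 3.230, 3.473, 3.387, 3.450, 3.882, 3.707]
  couplings:
    - [1, 2, 8.0]
    - [2, 3, 9.1]
    - [3, 4, 9.4]
    - [4, 5, 8.9]
    - [5, 6, 1.6]
    - [5, 7, 5.4]
    - [6, 7, -12.3]
  reference_concentration_mM: 1.16

- name: Thr
  shifts: [3.578, 4.246, 1.316, 1.316, 1.316]
  couplings:
    - [1, 2, 4.917]
    - [2, 3, 6.35]
    - [2, 4, 6.35]
    - [2, 5, 6.35]
  reference_concentration_mM: 0.33

# GABA: spins 1,2 = C4-H2 (edited 3.0 ppm resonance), 3,4 = C3-H2 (1.9 ppm,
# editing target), 5,6 = C2-H2 (2.28 ppm).
- name: GABA
  shifts: [3.0128, 3.0128, 1.889, 1.889, 2.284, 2.284]
  couplings:
    - [1, 3, 5.372]
    - [1, 4, 7.127]
    - [2, 3, 10.578]
    - [2, 4, 6.982]
    - [3, 5, 7.755]
    - [3, 6, 7.432]
    - [4, 5, 6.173]
    - [4, 6, 7.933]
  reference_concentration_mM: 1.5

- name: Cr_CH3
  metabolite: Cr
  scale: 3
  shifts: [3.027]
  couplings: []
  reference_concentration_mM: 8.0

- name: Cr_CH2
  metabolite: Cr
  scale: 2
  shifts: [3.913]
  couplings: []
  reference_concentration_mM: 8.0

- name: NAA_acetyl
  metabolite: NAA
  scale: 3
  shifts: [2.008]
  couplings: []
  reference_concentration_mM: 12.25

- name: NAA_aspartyl
  metabolite: NAA
  scale: 1
  shifts: [4.382, 2.6727, 2.4863]
  couplings:
    - [1, 2, 3.861]
    - [1, 3, 9.821]
    - [2, 3, -15.592]
  reference_concentration_mM: 12.25
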