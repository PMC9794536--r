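# Subcomponent material parameters, cell type 1 (chondrocyte-like).
# Units in key names: MPa, 1/MPa, s. C10/D1 are the tabulated Neo-Hookean
# values (3 significant figures); they are re-derived and cross-checked
# against (E, nu) on read.
label: cell type 1
materials:
  cytoplasm:
    E_MPa: 1.28e-3
    nu: 0.37
    C10_MPa: 2.33e-4
    D1_perMPa: 1.22e+3
    E_R_MPa: 4.50e-4
    tau_sigma_s: 19.7
    tau_epsilon_s: 9.5
  microtubule:
    E_MPa: 1.53e+4
    nu: 0.38
    C10_MPa: 2.78e+3
    D1_perMPa: 9.39e-5
  microfilament:
    E_MPa: 3.32e+4
    nu: 0.38
    C10_MPa: 6.02e+3
    D1_perMPa: 4.33e-5
  membrane:
    E_MPa: 1.28e-2
    nu: 0.30
    C10_MPa: 2.46e-3
    D1_perMPa: 1.88e+2
  nucleus:
    E_MPa: 5.11e-3
    nu: 0.37
    C10_MPa: 9.33e-4
    D1_perMPa: 3.05e+2
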