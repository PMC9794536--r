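# Subcomponent material parameters, cell type 2 (softer variant: every
# modulus about one order of magnitude below cell type 1).
label: cell type 2
materials:
  cytoplasm:
    E_MPa: 1.00e-4
    nu: 0.37
    C10_MPa: 1.83e-5
    D1_perMPa: 1.56e+4
    E_R_MPa: 4.50e-4
    tau_sigma_s: 19.7
    tau_epsilon_s: 9.5
  microtubule:
    E_MPa: 1.20e+3
    nu: 0.38
    C10_MPa: 2.17e+2
    D1_perMPa: 1.20e-3
  microfilament:
    E_MPa: 2.60e+3
    nu: 0.38
    C10_MPa: 4.71e+2
    D1_perMPa: 5.54e-4
  membrane:
    E_MPa: 1.00e-3
    nu: 0.30
    C10_MPa: 1.92e-4
    D1_perMPa: 2.40e+3
  nucleus:
    E_MPa: 4.00e-4
    nu: 0.37
    C10_MPa: 7.30e-5
    D1_perMPa: 3.90e+3
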