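# Published parameter estimates for the PDE7A/PDE4B inhibitor GRMS-55 in
# ConA-induced hepatitis (female BALB/c mice; IP doses 50 and 100 mg/kg,
# IV ConA 20 mg/kg at 0.5 h post-dose).
#
# Baselines (R0) are study-specific inputs and are deliberately NOT part of
# this file: supply them via the `baselines` argument of read_parameters()
# (see default_baselines() for the documented package assumptions).
pk:
  Vd_F: 1.81    # apparent volume of distribution, L/kg (bioavailability folded in)
  ka: 1.49      # absorption rate constant, 1/h (flip-flop: ka < ke)
  ke: 4.59      # elimination rate constant, 1/h
tau: 0.405      # mean transit time of precursor compartments, h
tnf:
  IC50: 7.97    # mg/L
  S: 453.9
  kout: 0.209   # 1/h
  Imax: 1       # fixed
ifn:
  IC50: 12.27
  S: 5856
  kout: 0.234
  Imax: 1
il6:
  IC50: 13.40
  S: 10320
  kout: 0.531
  Imax: 1
il10:
  S: 2.035
  kout: 1.841
  kin_dis: 160.8   # ng/L/h, disease-state production, active post-challenge
  I_ifn: 0.0002    # L/ng, linear inhibition of IL-10 production by IFN-gamma
disease:
  S_ALT_TNF: 0.0072
  S_ALT_IFN: 0.0002
  kout_ALT: 0.0997
  S_AST_TNF: 0.7727
  S_AST_IFN: 0.0007
  kout_AST: 0.0817
  alpha: 1.5    # fixed structural exponent
  beta: 1.5     # fixed structural exponent
conA_time: 0.5  # h after the drug dose
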