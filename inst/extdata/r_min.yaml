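# Zero-Ca2+ calibration solution (concentrations in mM)
compounds:
  KCl: 129.5
  KOH: 13.0
  NaCl: 15.0
  MgCl2: 1.0
  HEPES: 5.0
  EGTA: 4.0
  fura-2: 0.05
pH: 7.2
temperature_C: 22
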