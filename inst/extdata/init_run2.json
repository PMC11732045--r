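{
  "S_S1": 57, "S_H1_0": 280, "S_H2_0": 178,
  "X_H1": 1200, "X_STO1": 16, "total_biomass": 1891, "bound_cod": 85
}
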