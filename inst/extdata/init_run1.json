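{
  "S_S1": 57, "S_H1_0": 335, "S_H2_0": 208,
  "X_H1": 1450, "X_STO1": 10, "total_biomass": 2010, "bound_cod": 0
}
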