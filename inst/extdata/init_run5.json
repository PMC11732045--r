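{
  "S_S1": 68, "S_H1_0": 390, "S_H2_0": 229,
  "X_H1": 1000, "X_STO1": 0, "total_biomass": 1846, "bound_cod": 33
}
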