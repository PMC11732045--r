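{
  "S_S1": 68, "S_H1_0": 402, "S_H2_0": 225,
  "X_H1": 932, "X_STO1": 0, "total_biomass": 1640, "bound_cod": 25
}
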