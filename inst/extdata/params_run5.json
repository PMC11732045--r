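{
  "mu_H": 5.2, "K_S": 50, "b_H": 0.27, "K_OH": 0.01,
  "k_h1": 3.8, "K_X": 0.15, "k_h2": 0.56, "K_XX": 0.05,
  "k_STO": 0, "K_STO": 0, "mu_STO": 0,
  "Y_H": 0.6, "Y_STO": 0.8, "f_ES": 0.05, "f_EX": 0.15, "Y_SP": 0.06
}
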