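{
  "epinephrine": {
    "Vd": 20,
    "f1": 8,
    "c1": 20,
    "c2": 1.5,
    "c3": 3,
    "d1": 30,
    "d2": 0.1,
    "d3": 40,
    "CE0": 200,
    "cag_star": 5
  },
  "controller": {
    "CI0": 60,
    "CG0": 28.7,
    "k1": 0.002,
    "k2": 0.001,
    "k3": 0.001,
    "k4": 0.0014,
    "k5": 3.6e-05,
    "D": 0.1,
    "phi_constant": 1,
    "psi_constant": 1
  },
  "bw": 70,
  "derived": {
    "k": 0.166041815842246,
    "h": 0.1
  }
}
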