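grn:
  p:
    p1: 0.1
    p2: 1.0
    p3: 5.0
    p4: 1.0
    p5: 1.5
    p6: 0.01
    p7: 0.5
    p8: 0.7
    p9: 0.5
    p10: 1.0
    p11: 0.2
    p12: 2.5
    p13: 2.6
    p14: 2.0
    p15: 1.0
    p16: 0.01
  gamma:
    R: 0.15
    T: 0.15
    G: 0.23
    P: 0.06
    X: 0.02
  kd_factor:
    R: 1.0
    T: 1.0
    G: 1.0
    P: 1.0
    X: 1.0
    'N': 1.0
epigenetic:
  rates:
    k1: 0.28
    k2: 0.2
    k3: 0.2
    alpha: 0.002
    beta: 0.002
    gammaM: 0.0005
    delta: 0.0005
    epsilon: 0.002
  sites: 500
  open_fraction_threshold: 0.75
division:
  mu:
  - 34.0
  - 15.0
  - 13.0
  - 12.0
  - 12.0
  sigma:
  - 13.0
  - 5.0
  - 5.0
  - 4.0
  - 3.0
initial_state:
  R: 1.0
  T: 2.0
  G: 1.0
  P: 5.0
  X: 8.0
  'N': 7.0
initial_region:
  C: 500
  I: 0
  O: 0
horizon: 120.0
knockdown: ~
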