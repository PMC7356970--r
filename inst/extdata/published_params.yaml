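pk:
  cl: 6.4
  v: 11.4
  v2: 45.399999999999999
  v3: 1006.0
  q2: 2.6
  q3: 3.3
  ka: 1.09
  ktr: 1.1
  n_transit: 5
bioavailability:
  bmax: 1.6
  ba50: 90.099999999999994
  alpha_low: 0.002
  alpha_high: 0.0
  dose_threshold: 400.0
cetp:
  cetp_base: 350.0
  kin_base: 164.0
  kmax: 9.6
  k50: 9700.0
  emax: 18.199999999999999
  ec50: 587.0
hdl:
  rb: 50.0
  ksyn: 1.26
  rmax: 1.5
  r50: 185.0
  gamma: 2.1
  beta: 0.0
  direction: stimulation
  reference_cetp: 350.0
ldl:
  rb: 97.400000000000006
  ksyn: 0.435
  rmax: 0.8
  r50: 80.700000000000003
  gamma: 2.2
  beta: 0.0009
  direction: inhibition
  reference_cetp: 350.0
iiv:
  pk:
    cl: 15.6
    v3: 58.100000000000001
    bmax: 28.199999999999999
    ktr: 14.1
  cetp:
    kin_base: 19.699999999999999
    emax: 39.5
  hdl:
    rb: 17.199999999999999
  ldl:
    rb: 23.600000000000001
    beta: 97.400000000000006
    gamma: 50.899999999999999
residual:
  pk:
    add: 0.0001
    prop: 0.3
  cetp:
    add: 40.399999999999999
    prop: 0.112
  hdl:
    add: 4.6
    prop: 0.0
  ldl:
    add: 0.0
    prop: 0.07
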