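params:
  ka: 3.12
  lag: 0.31
  cl: 17.6
  v2: 210.0
  q: 37.6
  v3_factor: 1.0
  q2: 80.5
  v4: 26.7
  kd: 0.929
  svap1c: 5.52
  f_mvap1c: 2.13
  f_mvap1p1: 52.0
  f_mvap1p2: 1.0
  sl: 851.0
  pow: 0.851
  emax_egfr_cl: 1.3
  ec50_egfr_cl: 77.0
  hill_egfr_cl: 10.0
  pow_egfr_f1: -0.257
  sex_vap1: 0.125
  egfr_ref_f1: 44.0
variability:
  omega:
  - - 0.128
    - 0.0213
    - -0.0301
  - - 0.0213
    - 0.0735
    - -0.0222
  - - -0.0301
    - -0.0222
    - 0.0574
  sigma2_pk: 0.115
  sigma2_svap1: 0.0351
  sigma2_act: 0.0696
  phase2_factor: 1.88
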