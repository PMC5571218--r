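geometry:
  R_outer: 2.5
  R_inner: 1.75
  opening_angle: 1.4
  length_ref: 10.0
composition:
  media_fraction: 0.6666667
  media:
    IL: 0.15
    E: 0.25
    C: 0.2
    SMC: 0.4
  adventitia:
    IL: 0.0
    E: 0.3
    C: 0.7
    SMC: 0.0
microstructure:
  mode: full
  adv_elastin:
    components:
    - mean_angle: 0.25
      sd_angle: 0.17
      support:
      - 0.0
      - 3.1415927
    - mean_angle: 1.84
      sd_angle: 0.38
      support:
      - 0.0
      - 3.1415927
    weights:
    - 0.5
    - 0.5
  adv_collagen:
    components:
    - mean_angle: 0.32
      sd_angle: 0.23
      support:
      - 0.0
      - 3.1415927
    - mean_angle: 1.81
      sd_angle: 0.33
      support:
      - 0.0
      - 3.1415927
    weights:
    - 0.5
    - 0.5
  adv_recruitment:
    kind: beta
    shape1: 30.2632257
    shape2: 56.2031334
    lower: 0.0
    upper: 1.0
    point_value: ~
  media_fiber:
    mean_angle: 0.23
    sd_angle: 0.19
    support:
    - 0.0
    - 1.5707963
  media_smc:
    mean_angle: 0.24
    sd_angle: 0.21
    support:
    - 0.0
    - 1.5707963
  media_recruitment:
    kind: uniform
    shape1: ~
    shape2: ~
    lower: 0.0
    upper: 0.35
    point_value: ~
passive:
  k_IL: 0.18
  k_E: 0.27
  k_C: 29.5
  M_C: 5.23
active:
  rho1: 0.31
  rho2: 1.43
  lam_max: 1.34
  sigma_max: 0.09
  tau: 0.23
  k_smc_radial: 0.01
  activation: 1.0
  clamp: yes
quadrature:
  n_angle: 64
  n_recruit: 32
  n_radial: 64
protocol:
  pressures:
  - 0.0
  - 20.0
  - 40.0
  - 60.0
  - 80.0
  - 100.0
  - 120.0
  - 140.0
  - 160.0
  stretches:
  - 1.3
  - 1.5
  states:
  - passive
  - full
seed: 1.0
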