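spec:
  K: 6.0
  Q: 2.0
  times:
  - 0.0
  - 1.0
  - 2.0
  loading:
    mode: confirmatory
    mask:
    - - 1
      - 0
    - - 1
      - 0
    - - 1
      - 0
    - - 0
      - 1
    - - 1
      - 0
    - - 0
      - 1
    fixed:
    - - 0.0
      - 0.0
    - - 0.0
      - 0.0
    - - 0.0
      - 0.0
    - - 0.0
      - 0.0
    - - 0.0
      - 0.0
    - - 0.0
      - 0.0
    anchors:
    - 1
    - 4
  level2:
    fixed:
    - t
    - t2
    - D:t
    - D:t2
    random:
    - t
    - t
    baseline_balance: yes
  compliance_covariates: []
  eps_var: 1.0
  outcome_names:
  - y1
  - y2
  - y3
  - y4
  - y5
  - y6
params:
  lambda0_c:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  lambda0_n:
  - -1.0
  - -1.0
  - -1.0
  - -1.0
  - -1.0
  - -1.0
  loadings:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  beta_c:
    beta[c,1,t]: 0.5
    beta[c,1,t2]: -0.1
    beta[c,1,D:t]: 1.5
    beta[c,1,D:t2]: 0.0
    beta[c,2,t]: 0.5
    beta[c,2,t2]: -0.1
    beta[c,2,D:t]: 1.5
    beta[c,2,D:t2]: 0.0
  beta_n:
    beta[n,1,t]: 0.2
    beta[n,1,t2]: -0.05
    beta[n,2,t]: 0.2
    beta[n,2,t2]: -0.05
  xi_c:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  xi_n:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  tau2_c:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  tau2_n:
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  sigma_v:
  - - 0.5
  - - 0.5
  eta:
    (Intercept): -0.8472979
trial:
  n_subjects: 200.0
  allocation: 0.5
  fixed_allocation: no
  missingness:
    control:
    - 0.061
    - 0.143
    treated:
    - 0.244
    - 0.222
  compliance_covariate: ~
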