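space:
  labels:
  - ba
  - da
  - ga
  prototypes:
    ba:
    - 0.0
    - 0.0
    da:
    - 0.346835959474356
    - 0.559506050991325
    ga:
    - 1.0
    - 1.0
  category_sd: 0.048931106678021
  priors:
  - 0.333333333333333
  - 0.333333333333333
  - 0.333333333333333
noise:
  sigma_a: 0.125606211276135
  sigma_v: 0.114903573660605
  anisotropy: 1.5
model:
  prior_common: 0.5
  n_trials: 10000
  strategy: averaging
  c2_eval: fused
  seed: 1
meta:
  calibrated: yes
  method: grid search + multi-start Nelder-Mead refinement, RMSE objective with forced-fusion
    baseline-signature constraint
  behavior: inst/extdata/behavior-reported.csv
  loss_rmse: 0.018542422403004
  n_trials_eval: 2000
  calibration_seed: 1.0
  date: '2026-09-28'
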