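# Demo configuration for run_pipeline(): a small synthetic study that runs
# end-to-end in a few minutes on one CPU. Any field of pipeline_config()
# can be overridden here.
seed: 7
n_trials_per_level: 60
generator:
  model: nbm
  kappa_loc: 12
  kappa_feat: 5
  gain: 30
  conjunction:
    low: 0.35
    medium: 0.55
    high: 0.8
predictor:
  n_iter: 500
randomization:
  n_iter: 200
fit:
  models: [nbm, im_full, im_partial]
  nbm_restarts: 1
  nbm_maxit: 200
  im_restarts: 2
  im_maxit: 300
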