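# Demo pipeline configuration: a small fully synthetic study.
seed: 1
stages: [rdm, compare, ceiling, categoricality, reweight, categorize]
synthetic:
  n_stimuli: 24
  n_features: 40
  n_models: 3
  n_subjects: 4
  subject_noise_sd: 0.15
  tightness:
    animate: 1.0
    inanimate: 0.5
params:
  n_perm: 499
  n_boot: 300
  n_rand: 199
  holdout_size: 4
  k: 6
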