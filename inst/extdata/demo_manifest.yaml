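# Demo run manifest: a scaled-down end-to-end pass over every analysis
# stage, from simulation through segmentation, features and statistics.
seed: 20260919
config:
  image_shape: [192, 192]
  n_objects_per_field: 12
  n_events: 4000
  droplet_density: 15
  n_fields: 30
stages:
  - stage: mito
    params:
      n_experiments: 3
      n_fields: 3
      fragmentation_control: 0.3
      fragmentation_mutant: 0.8
  - stage: droplets
    params:
      n_experiments: 4
      area_scale_mutant: 1.5
  - stage: tmrm
    params:
      n_experiments: 4
  - stage: flux
  - stage: emcounts
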