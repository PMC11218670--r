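# Orthogonal-view 90-degree desk-scale experiment: synthesizes a paired
# prior/current phantom, projects, trains variant A and B score models, and
# reconstructs with FDK, ADMM-TV, PFGDM-A and PFGDM-B.
seed: 1
methods: [fdk, admm_tv, pfgdm_a, pfgdm_b]
phantom:
  n: 64
  n_slices: 3
geometry:
  mode: ortho
  total_angle: 90
  sampling_density: 0.25
train:
  n_volumes: 40
  hidden: 12
  iterations: 4000
pfgdm:
  total_steps: 150
admm_tv:
  tv_weight: 3
  penalty: 30
  outer_iters: 40
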