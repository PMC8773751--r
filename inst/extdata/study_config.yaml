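# Study-scale synthetic design: 2 groups x 18 participants x 32 displays,
# truncated-Poisson fixation counts, reference TD/ASD matrices as truth.
seed: 1
n_participants_per_group: 18
n_displays: 32
fixations_per_display:
  kind: poisson_truncated
  mean: 10
  min: 2
groups:
  TD:
    initial_distribution: stationary
    transition_matrix:
      - [0.43, 0.46, 0.11]
      - [0.18, 0.74, 0.08]
      - [0.25, 0.55, 0.20]
  ASD:
    initial_distribution: stationary
    transition_matrix:
      - [0.36, 0.49, 0.15]
      - [0.15, 0.70, 0.15]
      - [0.14, 0.37, 0.49]
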