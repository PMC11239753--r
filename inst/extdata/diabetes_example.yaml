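# Six-period closed-cohort stepped wedge with individually randomized
# education/coaching (IL) and town-level ride vouchers (CL); continuous
# HbA1c outcome on the standardized scale. Incremental effects scaled so
# each coefficient is the effect after three periods (six months).
design:
  n_periods: 6
  n_sequences: 5
  clusters_per_sequence: 13
  cohort_size: 15
  il_split: 0.5
  cohort_type: closed_cohort
mean_model:
  effect_model: incremental
  time_trend: linear
  link: identity
  theta: [0.0, 0.0, 0.1, 0.15, -0.1]
  scaling:
    il: 3
    cl: 3
    int: 3
correlation:
  family: block_exchangeable
  alpha:
    within_period: 0.05
    inter_period: 0.025
    within_individual: 0.5
variance:
  family: gaussian
  dispersion: 1.0
contrasts:
  - label: combined
    L: [0, 0, 1, 1, 1]
    family: primary
  - label: il
    L: [0, 0, 1, 0, 0]
    family: secondary
  - label: cl
    L: [0, 0, 0, 1, 0]
    family: secondary
  - label: interaction
    L: [0, 0, 0, 0, 1]
    alpha: 0.05
    include_in_search: false
multiplicity:
  - name: primary
    alpha: 0.05
    adjust: bonferroni
  - name: secondary
    alpha: 0.1
    adjust: bonferroni
power_goal: 0.8
n_max: 500
simulation:
  n_replicates: 2000
  seed: 20240515
  generator: gaussian_exact
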