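scenario: 1
name: rw_learning_rate_estimation
description: >
  Accurate estimation of the Rescorla-Wagner learning rate from a
  single-cue classical conditioning experiment. The reference design is
  acquisition under 50% partial reinforcement followed by extinction; the
  optimized structure is one cue with a periodically switching reinforcement
  probability (design variables: the two levels P1 and P2 and the
  half-period T; 3 variables).
model_space: [rw]
analysis: estimate
target_param: alpha
utility: negative_absolute_estimation_error
reference_design:
  name: acquisition_extinction
  n_trials: 160
  p_acquisition: 0.5
  assumed: true
  provenance: >
    Reinforcement probabilities 0.5 (acquisition) and 0 (extinction) with a
    single mid-experiment switch are stated in the source study; the trial
    count is not printed there (supplementary material only), so 160 trials
    (80 + 80) is a package default.
sigma_obs:
  value: 0.1
  assumed: true
  provenance: >
    The source study describes only "moderate levels of observation noise";
    0.1 response-scale units is a package default.
evaluation_priors:
  LA: {alpha: 0.1}
  MA: {alpha: 0.2}
  HA: {alpha: 0.3}
design_priors:
  vague:
    rw:
      alpha: {uniform: [0.0, 1.0]}
      sigma_obs: {uniform: [0.01, 1.0]}
  point:
    # The point design prior coincides with the chosen evaluation prior;
    # alpha is filled in at run time from the evaluation prior in use.
    rw:
      alpha: {point: 0.2}
      sigma_obs: {point: 0.1}
design_space:
  parameterization: periodic
  n_trials: 160
evaluation_sims_per_prior: 256
optimization:
  iterations: 300
  n_initial_points: 10
  sims_per_evaluation: 32
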