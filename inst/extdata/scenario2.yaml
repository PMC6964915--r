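scenario: 2
name: rw_vs_krw_model_selection
description: >
  Model selection between the Rescorla-Wagner model and its Kalman-filter
  extension (KRW). The reference design is backward blocking: a stage of
  reinforced compound (AB+) trials, a stage of reinforced element (A+)
  trials, and a short non-reinforced test stage presenting A and B
  separately. The optimized structure is two stages with three presentable
  stimuli (A, B, AB) and stage-wise contingencies (10 non-redundant design
  variables).
model_space: [rw, krw]
analysis: select
utility: model_selection_accuracy
reference_design:
  name: backward_blocking
  stage_trials: [20, 20, 10]
  assumed: true
  provenance: >
    Stage structure (AB+ then A+ then non-reinforced test of A and B) is
    stated in the source study; per-stage trial counts are not printed there
    (supplementary material only), so 20/20/10 is a package default.
sigma_obs:
  value: 0.1
  assumed: true
  provenance: >
    Noise level described only as moderate; 0.1 is a package default.
point_params:
  assumed: true
  provenance: >
    The source study set these at the values of the Kruschke (2008)
    backward-blocking simulations, which are not reproduced in its main
    text; the values below are representative package defaults in the same
    regime (unit prior weight variance, small weight drift, moderate outcome
    noise).
  rw:
    alpha: 0.2
  krw:
    w0_var: 1.0
    q_diffusion: 0.01
    r_noise_var: 0.2
vague_params:
  provenance: >
    Uniform for bounded parameters, weakly-informative half-normal for
    variance parameters.
  rw:
    alpha: {uniform: [0.0, 1.0]}
    sigma_obs: {uniform: [0.01, 1.0]}
  krw:
    w0_var: {halfnormal: 1.0}
    q_diffusion: {halfnormal: 0.1}
    r_noise_var: {halfnormal: 0.5}
    sigma_obs: {uniform: [0.01, 1.0]}
design_space:
  parameterization: stage-wise
  stage_trials: [25, 25]
evaluation_sims_per_model: 256
optimization:
  iterations: 300
  n_initial_points: 10
  sims_per_evaluation: 32
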