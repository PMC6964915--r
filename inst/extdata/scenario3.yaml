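scenario: 3
name: rw_vs_rwph_response_mapping_selection
description: >
  Model selection between the Rescorla-Wagner model (RW(V)) and three
  variants of the hybrid Rescorla-Wagner/Pearce-Hall model that emit
  different quantities as the conditioned response: weights (RWPH(V)),
  associabilities (RWPH(alpha)), or their mixture (RWPH(V+alpha)). The
  reference design is reversal learning with two cues: one cue partially
  reinforced and one unreinforced, with roles swapped mid-experiment. The
  optimized structure is two stages with two cues and stage-wise
  contingencies (6 non-redundant design variables).
model_space: [rw, rwph_v, rwph_alpha, rwph_valpha]
analysis: select
utility: model_selection_accuracy
reference_design:
  name: reversal_learning
  stage_trials: [60, 60]
  p_reinforced: 0.7
  assumed: true
  provenance: >
    Two-stage role-swap structure is stated in the source study; per-stage
    trial counts and the partial reinforcement rate are not printed there,
    so 60 + 60 trials at 0.7 reinforcement is a package default.
sigma_obs:
  value: 0.1
  assumed: true
  provenance: >
    Noise level described only as moderate; 0.1 is a package default.
point_params:
  assumed: true
  provenance: >
    The source study used the best-fitting RWPH(V+alpha) parameters of Li et
    al. (2011), which are not reproduced in its main text; the values below
    are representative package defaults. The other models use nested subsets
    of these parameters (for RW, alpha = kappa * alpha0).
  rw:
    alpha: 0.3
  rwph_v:
    kappa: 0.3
    eta: 0.5
    alpha0: 1.0
  rwph_alpha:
    kappa: 0.3
    eta: 0.5
    alpha0: 1.0
  rwph_valpha:
    kappa: 0.3
    eta: 0.5
    alpha0: 1.0
    omega: 0.5
vague_params:
  provenance: Uniform priors for all bounded parameters.
  rw:
    alpha: {uniform: [0.0, 1.0]}
    sigma_obs: {uniform: [0.01, 1.0]}
  rwph_v:
    kappa: {uniform: [0.0, 1.0]}
    eta: {uniform: [0.0, 1.0]}
    alpha0: {uniform: [0.0, 1.0]}
    sigma_obs: {uniform: [0.01, 1.0]}
  rwph_alpha:
    kappa: {uniform: [0.0, 1.0]}
    eta: {uniform: [0.0, 1.0]}
    alpha0: {uniform: [0.0, 1.0]}
    sigma_obs: {uniform: [0.01, 1.0]}
  rwph_valpha:
    kappa: {uniform: [0.0, 1.0]}
    eta: {uniform: [0.0, 1.0]}
    alpha0: {uniform: [0.0, 1.0]}
    omega: {uniform: [0.0, 1.0]}
    sigma_obs: {uniform: [0.01, 1.0]}
design_space:
  parameterization: stage-wise
  stage_trials: [60, 60]
evaluation_sims_per_model: 256
optimization:
  iterations: 300
  n_initial_points: 10
  sims_per_evaluation: 32
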