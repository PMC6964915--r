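#' Reference designs from the conditioning literature
#'
#' Three manual designs commonly used in associative-learning studies:
#'
#' * `acquisition_extinction` -- one cue, reinforced at `p_acquisition`
#'   (default 0.5) for the first half of the experiment and never reinforced
#'   in the second half (a periodic design with half-period 0.5).
#' * `backward_blocking` -- stage 1 presents only the reinforced compound AB;
#'   stage 2 presents only the reinforced element A; a final non-reinforced
#'   test stage presents A and B equiprobably.
#' * `reversal_learning` -- two cues presented equiprobably; in stage 1 cue A
#'   is reinforced at `p_reinforced` (default 0.7) and B never; in stage 2
#'   the cues swap roles.
#'
#' @param name one of `"acquisition_extinction"`, `"backward_blocking"`,
#'   `"reversal_learning"`.
#' @param n_trials total trials (acquisition-extinction; default 160).
#' @param stage_trials per-stage trial counts (backward blocking: three
#'   stages, default `c(20, 20, 10)`; reversal: two stages, default
#'   `c(60, 60)`).
#' @param p_acquisition acquisition-stage reinforcement probability.
#' @param p_reinforced partial reinforcement rate of the reinforced cue.
#' @return a valid `cond_design`.
#' @examples
#' build_reference_design("backward_blocking")
#' @export
build_reference_design <- function(name = c("acquisition_extinction",
                                            "backward_blocking",
                                            "reversal_learning"),
                                   n_trials = 160, stage_trials = NULL,
                                   p_acquisition = 0.5, p_reinforced = 0.7) {
  name <- match.arg(name)
  switch(name,
    acquisition_extinction = {
      cs <- cue_set("A")
      periodic_design(cs, n_trials,
                      cue_p1 = c(A = 1), cue_p2 = c(A = 1),
                      outcome_p1 = c(A = p_acquisition),
                      outcome_p2 = c(A = 0),
                      half_period = 0.5)
    },
    backward_blocking = {
      if (is.null(stage_trials)) stage_trials <- c(20, 20, 10)
      stopifnot(length(stage_trials) == 3L)
      cs <- cue_set(c("A", "B"), compounds = list(c("A", "B")))
      stagewise_design(cs, list(
        design_stage(stage_trials[1], c(AB = 1), c(AB = 1)),
        design_stage(stage_trials[2], c(A = 1), c(A = 1)),
        design_stage(stage_trials[3], c(A = 0.5, B = 0.5),
                     c(A = 0, B = 0, AB = 0))))
    },
    reversal_learning = {
      if (is.null(stage_trials)) stage_trials <- c(60, 60)
      stopifnot(length(stage_trials) == 2L)
      cs <- cue_set(c("A", "B"))
      stagewise_design(cs, list(
        design_stage(stage_trials[1], c(A = 0.5, B = 0.5),
                     c(A = p_reinforced, B = 0)),
        design_stage(stage_trials[2], c(A = 0.5, B = 0.5),
                     c(A = 0, B = p_reinforced))))
    })
}

parse_param_prior <- function(spec) {
  if (is.numeric(spec) && length(spec) == 1L) return(prior_point(spec))
  if (!is.list(spec)) stop("cannot parse parameter prior: ", deparse(spec))
  if (!is.null(spec$point)) return(prior_point(spec$point))
  if (!is.null(spec$uniform)) {
    u <- unlist(spec$uniform)
    return(prior_uniform(u[1], u[2]))
  }
  if (!is.null(spec$halfnormal)) return(prior_halfnormal(spec$halfnormal))
  stop("unknown parameter-prior spec")
}

parse_model_priors <- function(lst, sigma_obs = NULL) {
  lst <- lst[setdiff(names(lst), c("provenance", "assumed"))]
  pp <- lapply(lst, function(params) {
    out <- lapply(params, parse_param_prior)
    if (is.null(out$sigma_obs) && !is.null(sigma_obs))
      out$sigma_obs <- prior_point(sigma_obs)
    out
  })
  design_prior(pp)
}

#' Load a shipped scenario configuration
#'
#' Reads one of the three scenario configuration files installed with the
#' package (or any YAML file with the same schema) and resolves it into R
#' objects: the reference design, the design space, the evaluation prior(s)
#' and the vague/point design priors. Numeric settings that the underlying
#' studies do not publish (per-stage trial counts, noise level, point-prior
#' parameter values) live in the config with `assumed`/`provenance` fields,
#' not in code.
#'
#' @param scenario 1, 2 or 3, or a path to a YAML config.
#' @return A `scenario_config` list; key fields: `scenario`, `model_space`,
#'   `analysis`, `reference_design`, `design_space`, `evaluation_priors`
#'   (named list of [design_prior()] objects), `design_priors` (named list
#'   with `vague` and `point`), `evaluation_n_sims`, `optimization`, `raw`.
#' @examples
#' cfg <- load_scenario_config(2)
#' cfg$design_space$dim  # 10
#' @export
load_scenario_config <- function(scenario) {
  path <- if (is.character(scenario) && file.exists(scenario)) scenario
          else system.file("extdata", sprintf("scenario%d.yaml", scenario),
                           package = "condesign", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  sigma <- raw$sigma_obs$value
  rd <- raw$reference_design
  reference <- switch(rd$name,
    acquisition_extinction = build_reference_design(
      "acquisition_extinction", n_trials = rd$n_trials,
      p_acquisition = rd$p_acquisition %||% 0.5),
    backward_blocking = build_reference_design(
      "backward_blocking", stage_trials = unlist(rd$stage_trials)),
    reversal_learning = build_reference_design(
      "reversal_learning", stage_trials = unlist(rd$stage_trials),
      p_reinforced = rd$p_reinforced %||% 0.7),
    stop("unknown reference design: ", rd$name))

  ds <- raw$design_space
  space <- if (identical(ds$parameterization, "periodic")) {
    design_space("periodic", reference$cues, n_trials = ds$n_trials)
  } else {
    design_space("stage-wise", reference$cues,
                 stage_trials = unlist(ds$stage_trials))
  }

  if (raw$scenario == 1) {
    evaluation_priors <- lapply(raw$evaluation_priors, function(p)
      design_prior(list(rw = list(alpha = prior_point(p$alpha),
                                  sigma_obs = prior_point(sigma)))))
    design_priors <- list(
      vague = parse_model_priors(raw$design_priors$vague),
      point = parse_model_priors(raw$design_priors$point))
    evaluation_n_sims <- raw$evaluation_sims_per_prior
  } else {
    evaluation_priors <- list(
      all = parse_model_priors(raw$point_params, sigma_obs = sigma))
    design_priors <- list(
      vague = parse_model_priors(raw$vague_params),
      point = parse_model_priors(raw$point_params, sigma_obs = sigma))
    evaluation_n_sims <- raw$evaluation_sims_per_model *
      length(raw$model_space)
  }

  structure(list(
    scenario = raw$scenario, name = raw$name,
    model_space = unlist(raw$model_space), analysis = raw$analysis,
    target_param = raw$target_param %||% "alpha",
    sigma_obs = sigma, reference_design = reference, design_space = space,
    evaluation_priors = evaluation_priors, design_priors = design_priors,
    evaluation_n_sims = evaluation_n_sims,
    optimization = raw$optimization, raw = raw),
    class = "scenario_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>", x$scenario, "-", x$name, "\n")
  cat("  models:", paste(x$model_space, collapse = ", "),
      "| analysis:", x$analysis,
      "| design space:", x$design_space$dim, "variables\n")
  invisible(x)
}

scenario_evaluate <- function(config, design, seed, n_sims = NULL,
                              n_starts = 5) {
  n_sims <- n_sims %||% config$evaluation_n_sims
  out <- list()
  for (j in seq_along(config$evaluation_priors)) {
    label <- names(config$evaluation_priors)[j]
    out[[label]] <- expected_design_utility(
      design, config$evaluation_priors[[j]],
      analysis = config$analysis, model_space = config$model_space,
      n_sims = n_sims, seed = derive_seed(seed, j),
      target_param = config$target_param, n_starts = n_starts)
  }
  out
}

read_evaluation_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$utilities <- as.numeric(x$utilities)
  structure(x, class = "expected_utility")
}

#' Run a scenario workflow stage end to end
#'
#' Executes one stage of the design-optimization workflow for a configured
#' scenario: evaluate the reference design, optimize the design, evaluate
#' the optimized design, or compare the evaluations. All stages are fully
#' seeded. When `out_dir` is given, designs are written as YAML, traces as
#' CSV and evaluations/reports as JSON; `mode = "compare"` can then consume
#' the files written by the earlier stages.
#'
#' @param config a [load_scenario_config()] result.
#' @param mode workflow stage.
#' @param seed master seed.
#' @param out_dir optional output directory (created if missing).
#' @param design_prior which design prior to optimize under
#'   (`"vague"` or `"point"`).
#' @param evaluation_prior label of the evaluation prior whose point value
#'   seeds the point design prior (scenario 1 only; default the middle one).
#' @param n_sims override of the evaluation simulation count.
#' @param optimization override list for the optimization options
#'   (`iterations`, `n_initial_points`, `sims_per_evaluation`).
#' @param optimized_design for `evaluate_optimized`/`compare` without
#'   `out_dir`: an `optimized_design` or `cond_design`.
#' @param reference_eval,optimized_eval for `compare` without `out_dir`:
#'   evaluation lists as returned by the earlier stages.
#' @param n_starts restarts per model fit.
#' @return A list describing the stage's results (designs, evaluations,
#'   trace, or comparison report, depending on `mode`).
#' @export
run_scenario <- function(config,
                         mode = c("evaluate_reference", "optimize",
                                  "evaluate_optimized", "compare"),
                         seed = 1, out_dir = NULL,
                         design_prior = c("vague", "point"),
                         evaluation_prior = NULL,
                         n_sims = NULL, optimization = list(),
                         optimized_design = NULL,
                         reference_eval = NULL, optimized_eval = NULL,
                         n_starts = 5) {
  mode <- match.arg(mode)
  design_prior <- match.arg(design_prior)
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  if (mode == "evaluate_reference") {
    evals <- scenario_evaluate(config, config$reference_design, seed,
                               n_sims = n_sims, n_starts = n_starts)
    if (!is.null(out_dir)) {
      write_design_yaml(config$reference_design,
                        file.path(out_dir, "reference_design.yaml"))
      for (label in names(evals))
        write_expected_utility_json(
          evals[[label]],
          file.path(out_dir, sprintf("eval_reference_%s.json", label)))
    }
    return(list(mode = mode, design = config$reference_design,
                evaluations = evals))
  }

  if (mode == "optimize") {
    prior <- config$design_priors[[design_prior]]
    if (config$scenario == 1 && design_prior == "point") {
      label <- evaluation_prior %||% names(config$evaluation_priors)[2L]
      prior <- config$evaluation_priors[[label]]
    }
    oo <- modifyList(config$optimization, optimization)
    opts <- bo_options(max_iterations = oo$iterations,
                       n_initial_points = oo$n_initial_points,
                       sims_per_evaluation = oo$sims_per_evaluation,
                       seed = seed, n_starts = n_starts)
    res <- optimize_design(config$design_space, prior,
                           analysis = config$analysis,
                           model_space = config$model_space,
                           options = opts,
                           target_param = config$target_param)
    if (!is.null(out_dir)) {
      write_design_yaml(res$design,
                        file.path(out_dir,
                                  sprintf("optimized_design_%s.yaml", design_prior)))
      write_trace_csv(res, file.path(out_dir,
                                     sprintf("trace_%s.csv", design_prior)))
    }
    return(list(mode = mode, design_prior = design_prior, result = res))
  }

  if (mode == "evaluate_optimized") {
    design <- optimized_design
    if (inherits(design, "optimized_design")) design <- design$design
    if (is.null(design)) {
      path <- file.path(out_dir %||% ".",
                        sprintf("optimized_design_%s.yaml", design_prior))
      if (!file.exists(path))
        stop("missing optimized design artifact: ", path)
      design <- read_design_yaml(path)
    }
    evals <- scenario_evaluate(config, design, seed, n_sims = n_sims,
                               n_starts = n_starts)
    if (!is.null(out_dir))
      for (label in names(evals))
        write_expected_utility_json(
          evals[[label]],
          file.path(out_dir, sprintf("eval_optimized_%s_%s.json",
                                     design_prior, label)))
    return(list(mode = mode, design = design, evaluations = evals))
  }

  # mode == "compare"
  labels <- names(config$evaluation_priors)
  if (is.null(reference_eval)) {
    reference_eval <- list()
    for (label in labels) {
      path <- file.path(out_dir %||% ".",
                        sprintf("eval_reference_%s.json", label))
      if (!file.exists(path))
        stop("missing reference evaluation artifact: ", path)
      reference_eval[[label]] <- read_evaluation_json(path)
    }
  }
  if (is.null(optimized_eval)) {
    optimized_eval <- list()
    for (label in labels) {
      path <- file.path(out_dir %||% ".",
                        sprintf("eval_optimized_%s_%s.json", design_prior, label))
      if (!file.exists(path))
        stop("missing optimized evaluation artifact: ", path)
      optimized_eval[[label]] <- read_evaluation_json(path)
    }
  }
  reports <- list()
  for (label in labels) {
    reports[[label]] <- compare_designs(
      list(optimized = optimized_eval[[label]],
           reference = reference_eval[[label]]),
      model_space = if (config$analysis == "select") config$model_space)
  }
  if (!is.null(out_dir))
    jsonlite::write_json(
      lapply(reports, unclass),
      file.path(out_dir, sprintf("comparison_%s.json", design_prior)),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  list(mode = mode, reports = reports)
}
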