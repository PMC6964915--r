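#' Priors over models and parameters for design evaluation
#'
#' A design prior specifies the distribution the simulated *ground truth* is
#' drawn from: a weight per candidate model, and per model a prior for each
#' generative parameter. Three parameter-prior forms are supported: a point
#' mass, a uniform box, and a (weakly informative) half-normal for
#' variance-type parameters.
#'
#' @param param_priors named list (one entry per model id); each entry is a
#'   named list of parameter priors built with [prior_point()],
#'   [prior_uniform()] or [prior_halfnormal()].
#' @param weights model weights (default uniform); must sum to 1.
#' @return A `design_prior` object.
#' @examples
#' pr <- design_prior(list(
#'   rw = list(alpha = prior_point(0.2), sigma_obs = prior_point(0.1))
#' ))
#' sample_ground_truth(pr)
#' @export
design_prior <- function(param_priors, weights = NULL) {
  model_idsv <- names(param_priors)
  if (is.null(model_idsv) || any(model_idsv == ""))
    stop("param_priors must be a named list keyed by model id")
  if (is.null(weights)) weights <- rep(1 / length(model_idsv), length(model_idsv))
  if (abs(sum(weights) - 1) > 1e-9) stop("model weights must sum to 1")
  structure(list(models = model_idsv, weights = setNames(weights, model_idsv),
                 param_priors = param_priors),
            class = "design_prior")
}

#' @param value the point-mass location.
#' @rdname design_prior
#' @export
prior_point <- function(value) structure(list(type = "point", value = value),
                                         class = "param_prior")

#' @param lo,hi uniform bounds.
#' @rdname design_prior
#' @export
prior_uniform <- function(lo, hi) structure(list(type = "uniform", lo = lo, hi = hi),
                                            class = "param_prior")

#' @param sd scale of the half-normal.
#' @param floor lower truncation (keeps variances strictly positive).
#' @rdname design_prior
#' @export
prior_halfnormal <- function(sd, floor = 1e-4)
  structure(list(type = "halfnormal", sd = sd, floor = floor),
            class = "param_prior")

sample_param <- function(pp) {
  switch(pp$type,
    point = pp$value,
    uniform = runif(1, pp$lo, pp$hi),
    halfnormal = max(abs(rnorm(1, 0, pp$sd)), pp$floor),
    stop("unknown parameter-prior type: ", pp$type))
}

#' Sample a ground truth (model + parameters) from a prior
#'
#' Draws a model according to the prior weights (unless `model_id` pins it,
#' as under balanced allocation) and then each parameter from its per-model
#' prior. Uses the current RNG state.
#'
#' @param prior a [design_prior()].
#' @param model_id optionally force the model (parameters still sampled).
#' @return list with `model_id` and `params` (named list).
#' @export
sample_ground_truth <- function(prior, model_id = NULL) {
  stopifnot(inherits(prior, "design_prior"))
  if (is.null(model_id)) {
    model_id <- sample(prior$models, 1L, prob = prior$weights)
  } else if (!model_id %in% prior$models) {
    stop("model ", model_id, " is not in the prior's support")
  }
  params <- lapply(prior$param_priors[[model_id]], sample_param)
  list(model_id = model_id, params = params)
}

#' Experiment-wise utility functions
#'
#' `estimation_utility()` is the negative absolute error between a parameter
#' estimate and its ground-truth value (maximization convention: 0 is
#' perfect). `selection_utility()` is the 0-1 correct-model indicator, whose
#' Monte-Carlo mean is the model-selection accuracy.
#'
#' @param estimate,truth parameter estimate and ground-truth value.
#' @return a numeric utility.
#' @examples
#' estimation_utility(0.25, 0.30)  # -0.05
#' selection_utility("rw", "krw")  # 0
#' @export
estimation_utility <- function(estimate, truth) -abs(estimate - truth)

#' @param selected,truth_model selected and ground-truth model ids.
#' @rdname estimation_utility
#' @export
selection_utility <- function(selected, truth_model)
  as.numeric(identical(selected, truth_model))

#' Monte-Carlo expected utility of a design
#'
#' For each of `n_sims` simulated experiments: sample a ground truth from the
#' prior, simulate a dataset under the design, run the planned analysis
#' (maximum-likelihood estimation of `target_param`, or BIC model selection
#' over `model_space`), and score the outcome with the experiment-wise
#' utility. The expected design utility is the average, reported with its
#' Monte-Carlo standard error. When the prior weights models equally, ground
#' truths are allocated in balanced, deterministic proportion (e.g. 32
#' datasets from each candidate model per evaluation); otherwise models are
#' sampled by weight. An analysis that fails inside a simulation is scored at
#' the configured worst case (never dropped): 0 for selection,
#' `failure_penalty` for estimation.
#'
#' @param design a valid `cond_design`.
#' @param prior a [design_prior()] for the simulated ground truth.
#' @param analysis `"estimate"` or `"select"`.
#' @param model_space character vector of candidate model ids fitted by the
#'   analysis (for `"estimate"`, its single element is the fitted model).
#' @param n_sims number of simulated experiments (>= 1).
#' @param seed master seed; per-simulation seeds are derived from it.
#' @param target_param estimated parameter name (analysis `"estimate"`).
#' @param n_starts restarts per model fit.
#' @param failure_penalty estimation utility recorded for a failed analysis.
#' @param bounds optional per-model bounds overrides passed to the fitters.
#' @return An `expected_utility` object: `mean`, `se`, `n_sims`, `seed`, the
#'   retained per-simulation `utilities`, `truth_models`, `selected` (model
#'   selection) or `estimates`/`truths` (estimation), and `n_failed`.
#' @examples
#' d <- stagewise_design(cue_set("A"), list(design_stage(30, c(A = 1), c(A = 0.5))))
#' pr <- design_prior(list(rw = list(alpha = prior_point(0.2),
#'                                   sigma_obs = prior_point(0.1))))
#' eu <- expected_design_utility(d, pr, analysis = "estimate",
#'                               model_space = "rw", n_sims = 4, seed = 1)
#' eu$mean
#' @export
expected_design_utility <- function(design, prior,
                                    analysis = c("estimate", "select"),
                                    model_space, n_sims, seed,
                                    target_param = "alpha", n_starts = 5,
                                    failure_penalty = -1, bounds = NULL) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(prior, "design_prior"), n_sims >= 1)
  schedule <- unroll_schedule(design)

  equal_w <- length(unique(round(prior$weights, 12))) == 1L
  truth_alloc <- if (equal_w) {
    rep(prior$models, length.out = n_sims)   # balanced allocation
  } else {
    with_seed(derive_seed(seed, 0L),
              sample(prior$models, n_sims, replace = TRUE, prob = prior$weights))
  }

  utilities <- numeric(n_sims)
  truth_models <- character(n_sims)
  selected <- rep(NA_character_, n_sims)
  estimates <- rep(NA_real_, n_sims)
  truths <- rep(NA_real_, n_sims)
  n_failed <- 0L

  for (i in seq_len(n_sims)) {
    si <- derive_seed(seed, i)
    gt <- with_seed(si, sample_ground_truth(prior, model_id = truth_alloc[i]))
    truth_models[i] <- gt$model_id
    ds <- simulate_dataset(schedule, gt$model_id, gt$params,
                           seed = derive_seed(si, 1L))
    res <- tryCatch({
      if (analysis == "estimate") {
        fit <- fit_mle(model_space[[1L]], ds, bounds = bounds[[model_space[[1L]]]],
                       n_starts = n_starts, seed = derive_seed(si, 2L))
        est <- fit$params[[target_param]]
        estimates[i] <- est
        truths[i] <- gt$params[[target_param]]
        estimation_utility(est, truths[i])
      } else {
        sel <- select_model(ds, model_space, n_starts = n_starts,
                            seed = derive_seed(si, 2L), bounds = bounds)
        selected[i] <- sel$winner
        selection_utility(sel$winner, gt$model_id)
      }
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      if (analysis == "estimate") failure_penalty else 0
    })
    utilities[i] <- res
  }

  structure(list(
    mean = mean(utilities),
    se = if (n_sims > 1L) sd(utilities) / sqrt(n_sims) else NA_real_,
    n_sims = as.integer(n_sims), seed = as.integer(seed),
    analysis = analysis, utilities = utilities,
    truth_models = truth_models, selected = selected,
    estimates = estimates, truths = truths, n_failed = n_failed),
    class = "expected_utility")
}

#' @export
print.expected_utility <- function(x, ...) {
  cat(sprintf("<expected_utility> mean %.4f (SE %.4f) over %d simulations\n",
              x$mean, x$se, x$n_sims))
  if (x$n_failed > 0) cat("  ", x$n_failed, "failed analyses scored as worst case\n")
  invisible(x)
}

#' Serialize an expected-utility evaluation as JSON
#'
#' Writes the mean, standard error, provenance (seed, number of simulations)
#' and the retained per-simulation utility vector.
#'
#' @param eu an `expected_utility`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expected_utility_json <- function(eu, path) {
  jsonlite::write_json(unclass(eu), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
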