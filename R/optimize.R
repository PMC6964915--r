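#' Options for Bayesian design optimization
#'
#' @param max_iterations total number of objective evaluations, including the
#'   space-filling initial points.
#' @param n_initial_points number of Latin-hypercube initial points
#'   (must be smaller than `max_iterations`).
#' @param sims_per_evaluation simulated datasets per candidate model in each
#'   expected-utility evaluation (e.g. 32 datasets from each candidate model).
#' @param seed master seed; per-evaluation seeds are derived from it, so the
#'   objective is reproducible but evaluations do not share random numbers.
#' @param acquisition acquisition function (expected improvement).
#' @param xi exploration offset added inside the expected-improvement
#'   criterion.
#' @param n_starts restarts per model fit inside each evaluation.
#' @return A validated `bo_options` list.
#' @export
bo_options <- function(max_iterations = 300, n_initial_points = 10,
                       sims_per_evaluation = 32, seed = 1,
                       acquisition = "ei", xi = 0.01, n_starts = 5) {
  stopifnot(max_iterations >= 1, n_initial_points >= 1)
  if (n_initial_points >= max_iterations)
    stop("n_initial_points must be smaller than max_iterations")
  acquisition <- match.arg(acquisition, "ei")
  structure(list(max_iterations = as.integer(max_iterations),
                 n_initial_points = as.integer(n_initial_points),
                 sims_per_evaluation = as.integer(sims_per_evaluation),
                 seed = as.integer(seed), acquisition = acquisition,
                 xi = xi, n_starts = as.integer(n_starts)),
            class = "bo_options")
}

bo_initial_points <- function(n, d, seed) {
  with_seed(derive_seed(seed, 555L), as.matrix(lhs::maximinLHS(n, d)))
}

# Maximize EI over [0,1]^d: dense random candidates plus local polish from
# the best few. The exploration offset xi is expressed on the standardized
# output scale. If the acquisition is degenerate (no point promises any
# improvement, as happens when the surrogate interpolates an exhausted
# noiseless objective), fall back to maximizing the posterior mean.
maximize_ei <- function(gp, d, xi, seed) {
  best <- max(gp_predict(gp, gp$X)$mean)
  xi_abs <- xi * gp$s
  n_cand <- max(512L, 128L * d)
  cand <- with_seed(derive_seed(seed, 17L),
                    matrix(runif(n_cand * d), ncol = d))
  polish <- function(obj, start, start_val) {
    res <- tryCatch(
      optim(start, obj, method = "L-BFGS-B", lower = 0, upper = 1,
            control = list(maxit = 100L)),
      error = function(e) NULL)
    if (!is.null(res) && res$value < start_val)
      list(v = pmin(pmax(res$par, 0), 1), val = res$value)
    else list(v = start, val = start_val)
  }
  pr <- gp_predict(gp, cand)
  ei <- expected_improvement(pr$mean, pr$sd, best, xi_abs)
  ord <- order(ei, decreasing = TRUE)
  neg_ei <- function(v) {
    p <- gp_predict(gp, matrix(v, nrow = 1))
    -expected_improvement(p$mean, p$sd, best, xi_abs)
  }
  best_v <- cand[ord[1L], ]
  best_val <- -ei[ord[1L]]
  for (i in 1:3) {
    out <- polish(neg_ei, cand[ord[i], ], -ei[ord[i]])
    if (out$val < best_val) {
      best_val <- out$val
      best_v <- out$v
    }
  }
  if (best_val >= -1e-14) {
    neg_mean <- function(v) -gp_predict(gp, matrix(v, nrow = 1))$mean
    ord_m <- order(pr$mean, decreasing = TRUE)
    best_v <- cand[ord_m[1L], ]
    best_val <- -pr$mean[ord_m[1L]]
    for (i in 1:3) {
      out <- polish(neg_mean, cand[ord_m[i], ], -pr$mean[ord_m[i]])
      if (out$val < best_val) {
        best_val <- out$val
        best_v <- out$v
      }
    }
  }
  best_v
}

#' Propose the next design vector to evaluate
#'
#' Before `n_initial_points` observations exist the proposal is the next
#' point of a deterministic Latin-hypercube space-filling set; afterwards a
#' Gaussian-process surrogate (Matern-5/2, fitted noise) is fit to the
#' observed (vector, utility) pairs and the expected-improvement acquisition
#' is maximized over the unit box by multi-start local search. If the GP fit
#' fails the proposal falls back to a uniform random point (with a warning).
#'
#' @param trace an optimization trace data frame as produced by
#'   [bo_maximize()]/[optimize_design()] (columns `utility` and `v1..vd`), or
#'   `NULL`/empty for the first proposal.
#' @param d dimensionality of the design space (or pass a [design_space()]).
#' @param seed integer seed.
#' @param n_initial_points size of the space-filling initial set.
#' @param xi exploration offset.
#' @return a vector in `[0, 1]^d`.
#' @export
propose_next <- function(trace, d, seed = 1, n_initial_points = 10, xi = 0.01) {
  if (inherits(d, "design_space")) d <- d$dim
  n_obs <- if (is.null(trace)) 0L else nrow(trace)
  if (n_obs < n_initial_points) {
    init <- bo_initial_points(n_initial_points, d, seed)
    return(init[n_obs + 1L, ])
  }
  X <- as.matrix(trace[, paste0("v", seq_len(d)), drop = FALSE])
  y <- trace$utility
  gp <- tryCatch(gp_fit(X, y, seed = derive_seed(seed, n_obs)),
                 error = function(e) NULL)
  if (is.null(gp)) {
    warning("GP fit failed; proposing a uniform random point")
    return(with_seed(derive_seed(seed, n_obs), runif(d)))
  }
  maximize_ei(gp, d, xi, derive_seed(seed, n_obs))
}

#' Bayesian optimization of a black-box objective over the unit box
#'
#' The core propose--evaluate--update loop: Latin-hypercube initial points,
#' then Gaussian-process expected-improvement proposals, for exactly
#' `max_iterations` objective evaluations. Because the observations are
#' (Monte-Carlo) noisy, the returned best point is the evaluated point with
#' the highest GP posterior mean, not the highest raw observation; the
#' trace's `incumbent` column is the running maximum of raw observations.
#'
#' @param f objective; called as `f(v, iteration)` and returning either a
#'   numeric utility or a list with `value` and `se`.
#' @param d dimensionality.
#' @param options a [bo_options()].
#' @return list with `best_v`, `best_index`, `best_observed`,
#'   `best_posterior_mean`, and the `trace` data frame
#'   (`iteration, utility, se, incumbent, v1..vd`).
#' @examples
#' res <- bo_maximize(function(v, i) -(v[1] - 0.7)^2, d = 1,
#'                    bo_options(max_iterations = 15, n_initial_points = 5))
#' res$best_v
#' @export
bo_maximize <- function(f, d, options = bo_options()) {
  n_iter <- options$max_iterations
  X <- matrix(NA_real_, n_iter, d)
  y <- numeric(n_iter)
  se <- rep(NA_real_, n_iter)
  init <- bo_initial_points(options$n_initial_points, d, options$seed)
  trace <- NULL
  for (it in seq_len(n_iter)) {
    v <- if (it <= options$n_initial_points) init[it, ]
         else propose_next(trace, d, seed = options$seed,
                           n_initial_points = options$n_initial_points,
                           xi = options$xi)
    out <- f(v, it)
    X[it, ] <- v
    if (is.list(out)) {
      y[it] <- out$value
      se[it] <- if (!is.null(out$se)) out$se else NA_real_
    } else {
      y[it] <- out
    }
    trace <- data.frame(iteration = seq_len(it), utility = y[seq_len(it)],
                        se = se[seq_len(it)],
                        incumbent = cummax(y[seq_len(it)]))
    vm <- as.data.frame(X[seq_len(it), , drop = FALSE])
    names(vm) <- paste0("v", seq_len(d))
    trace <- cbind(trace, vm)
  }
  gp <- tryCatch(gp_fit(X, y, seed = derive_seed(options$seed, 9999L)),
                 error = function(e) NULL)
  post_mean <- if (!is.null(gp)) gp_predict(gp, X)$mean else y
  best_i <- which.max(post_mean)
  list(best_v = X[best_i, ], best_index = best_i,
       best_observed = y[best_i], best_posterior_mean = post_mean[best_i],
       trace = trace)
}

#' Optimize a conditioning-experiment design by Bayesian optimization
#'
#' Runs [bo_maximize()] on the Monte-Carlo expected design utility: each
#' proposed vector is decoded through the design space's constraint-
#' preserving transform ([from_vector()]) and evaluated with
#' [expected_design_utility()] using `sims_per_evaluation` simulated datasets
#' per candidate model (per-evaluation seeds derived from the master seed and
#' the iteration). Identical configuration and seed give identical traces.
#'
#' @param space a [design_space()].
#' @param prior the design prior ([design_prior()]) used to simulate data
#'   during optimization.
#' @param analysis `"estimate"` or `"select"`.
#' @param model_space candidate model ids for the analysis.
#' @param options a [bo_options()].
#' @param target_param estimated parameter (analysis `"estimate"`).
#' @param bounds optional per-model fitting bounds overrides.
#' @return An `optimized_design`: list with `design` (decoded best), `vector`,
#'   `observed_utility`, `observed_se`, `posterior_mean_utility`, `trace`,
#'   and `space`.
#' @export
optimize_design <- function(space, prior, analysis = c("estimate", "select"),
                            model_space, options = bo_options(),
                            target_param = "alpha", bounds = NULL) {
  analysis <- match.arg(analysis)
  stopifnot(inherits(space, "design_space"))
  n_models <- length(prior$models)
  objective <- function(v, it) {
    design <- from_vector(space, v)
    eu <- expected_design_utility(
      design, prior, analysis = analysis, model_space = model_space,
      n_sims = options$sims_per_evaluation * n_models,
      seed = derive_seed(options$seed, 10000L + it),
      target_param = target_param, n_starts = options$n_starts,
      bounds = bounds)
    list(value = eu$mean, se = eu$se)
  }
  res <- bo_maximize(objective, space$dim, options)
  structure(list(design = from_vector(space, res$best_v),
                 vector = res$best_v,
                 observed_utility = res$best_observed,
                 observed_se = res$trace$se[res$best_index],
                 posterior_mean_utility = res$best_posterior_mean,
                 trace = res$trace, space = space),
            class = "optimized_design")
}

#' @export
print.optimized_design <- function(x, ...) {
  cat(sprintf("<optimized_design> observed utility %.4f (GP mean %.4f) after %d evaluations\n",
              x$observed_utility, x$posterior_mean_utility, nrow(x$trace)))
  print(x$design)
  invisible(x)
}

#' Write an optimization trace as CSV
#'
#' Columns: `iteration,utility,se,incumbent,v1..vd`.
#'
#' @param trace a trace data frame (or an `optimized_design`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (inherits(trace, "optimized_design")) trace <- trace$trace
  write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
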