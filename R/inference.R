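#' Maximum-likelihood fit of a learning model to a dataset
#'
#' Maximizes the Gaussian response likelihood over the model's dynamics
#' parameters with bounded quasi-Newton search (`optim(method = "L-BFGS-B")`)
#' from `n_starts` uniform-random interior starting points (drawn in the
#' central 5--95% of each bound). With uniform box priors this maximum a
#' posteriori estimate is the maximum-likelihood estimate. The observation
#' noise `sigma_obs` has a closed-form conditional maximum (the root mean
#' squared residual, clamped to its bounds) and is profiled out of the
#' search; it is still a fitted parameter and counts towards model
#' complexity. Variance-type parameters (KRW) are searched on log10 scale.
#'
#' @param model_id a model id (see [model_info()]).
#' @param dataset a `cond_dataset`.
#' @param bounds optional list with `lower`/`upper` named vectors overriding
#'   the model's default dynamics-parameter bounds.
#' @param n_starts number of random restarts (>= 1).
#' @param seed integer seed; fits are deterministic given the seed.
#' @param sigma_bounds bounds for the profiled `sigma_obs`.
#' @param cues optional [cue_set()] if the dataset lacks the attribute.
#' @return A `fit_result`: list with `model_id`, `params` (named list of all
#'   estimates, including `sigma_obs`), `loglik`, `k` (parameter count for
#'   BIC), `n_starts`, `converged`, `best_start`.
#' @examples
#' d <- stagewise_design(cue_set("A"), list(design_stage(40, c(A = 1), c(A = 0.5))))
#' ds <- simulate_dataset(d, "rw", list(alpha = 0.3, sigma_obs = 0.1), seed = 1)
#' fit_mle("rw", ds, seed = 1)$params$alpha
#' @export
fit_mle <- function(model_id, dataset, bounds = NULL, n_starts = 5, seed = 1,
                    sigma_bounds = c(0.01, 1), cues = NULL) {
  info <- model_info(model_id)
  if (is.null(cues)) cues <- attr(dataset, "cues")
  if (is.null(cues)) stop("dataset carries no cue_set; pass `cues`")
  n <- nrow(dataset)
  if (is.null(n) || n < 1L) stop("dataset has no trials")
  if (n_starts < 1L) stop("n_starts must be >= 1")
  enc <- encode_stimuli(dataset, cues)
  cr <- dataset$response

  lower <- if (!is.null(bounds$lower)) bounds$lower else info$lower
  upper <- if (!is.null(bounds$upper)) bounds$upper else info$upper
  logsc <- rep_len(info$log_scale, length(info$dyn_params))
  to_int <- function(th) ifelse(logsc, log10(th), th)
  to_nat <- function(th) ifelse(logsc, 10^th, th)
  lo_i <- to_int(lower)
  hi_i <- to_int(upper)

  profiled_nll <- function(th_int) {
    th <- setNames(to_nat(th_int), info$dyn_params)
    m <- model_mean_responses(model_id, as.list(th), enc$X, enc$r)$m
    rss <- sum((cr - m)^2)
    s2 <- min(max(rss / n, sigma_bounds[1]^2), sigma_bounds[2]^2)
    0.5 * n * log(2 * pi * s2) + rss / (2 * s2)
  }

  # Coarse screen, then local search: the likelihood surfaces of the hybrid
  # models are multimodal, so candidate points are first ranked by a cheap
  # profiled-likelihood evaluation and local searches start from the best.
  d <- length(lo_i)
  n_cand <- max(25L, 25L * d, 4L * n_starts)
  # candidates cover the closed box: nested sub-models live on its faces
  # (e.g. a frozen associability at eta = 0), which interior-only starts miss
  cand <- with_seed(seed, {
    matrix(runif(n_cand * d, rep(lo_i, each = n_cand),
                 rep(hi_i, each = n_cand)),
           nrow = n_cand)
  })
  cand_val <- apply(cand, 1, function(v)
    tryCatch(profiled_nll(v), error = function(e) Inf))
  starts <- cand[order(cand_val)[seq_len(n_starts)], , drop = FALSE]
  # nested sub-models live on boundary faces of the box (eta = 0 freezes the
  # associabilities; omega = 0/1 collapses the response mixture); add the
  # best face-projected candidate as an extra start so the richer model never
  # undercuts a model it nests
  for (face in info$faces) {
    fc <- cand
    j <- match(names(face), info$dyn_params)
    fc[, j] <- unname(face)
    fv <- apply(fc, 1, function(v)
      tryCatch(profiled_nll(v), error = function(e) Inf))
    starts <- rbind(starts, fc[which.min(fv), ])
  }

  best <- NULL
  best_start <- NA_integer_
  converged <- FALSE
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[s, ], profiled_nll, method = "L-BFGS-B",
            lower = lo_i, upper = hi_i,
            control = list(maxit = 500L, factr = 1e5, pgtol = 1e-8,
                           ndeps = rep(1e-6, d))),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      best_start <- s
      converged <- res$convergence == 0L
    }
  }
  if (is.null(best)) {
    # all starts failed: report the best raw start as a non-converged fit
    vals <- apply(starts, 1, function(v) tryCatch(profiled_nll(v), error = function(e) Inf))
    best <- list(par = starts[which.min(vals), ], value = min(vals))
    best_start <- which.min(vals)
    converged <- FALSE
  }
  th <- setNames(as.list(to_nat(best$par)), info$dyn_params)
  m <- model_mean_responses(model_id, th, enc$X, enc$r)$m
  rss <- sum((cr - m)^2)
  sigma_hat <- min(max(sqrt(rss / n), sigma_bounds[1]), sigma_bounds[2])
  th$sigma_obs <- sigma_hat
  structure(list(model_id = model_id, params = th, loglik = -best$value,
                 k = info$k, n_obs = n, n_starts = n_starts,
                 converged = converged, best_start = best_start),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model_id, "| loglik", format(x$loglik, digits = 6),
      "| k =", x$k, if (!x$converged) "| NOT converged", "\n")
  est <- unlist(x$params)
  cat(" ", paste(sprintf("%s=%.4g", names(est), est), collapse = "  "), "\n")
  invisible(x)
}

#' Bayesian information criterion
#'
#' `BIC = -2 * loglik + k * log(n)`; lower is better. The sample size is the
#' number of trials (one conditioned response per trial).
#'
#' @param loglik maximized log-likelihood.
#' @param k_params number of fitted parameters.
#' @param n_obs number of observations (>= 1).
#' @return the BIC value.
#' @examples
#' bic(-10, 2, 100)  # 29.21034
#' @export
bic <- function(loglik, k_params, n_obs) {
  if (!is.numeric(n_obs) || n_obs < 1) stop("n_obs must be >= 1")
  -2 * loglik + k_params * log(n_obs)
}

#' BIC model selection over a candidate model space
#'
#' Fits every candidate by [fit_mle()], computes BIC with `n` equal to the
#' number of trials, and selects the minimum. Exact BIC ties are broken
#' toward the model with fewer parameters, then by declaration order. The
#' per-model restart seeds are derived from the model id (not its position),
#' so the result does not depend on the order models are listed in.
#'
#' @param dataset a `cond_dataset`.
#' @param model_space character vector of at least two model ids.
#' @param n_starts restarts per fit.
#' @param seed integer seed.
#' @param bounds optional named list (per model id) of bounds overrides.
#' @param cues optional [cue_set()].
#' @return A `selection_result`: list with `winner`, `bic` (named vector),
#'   `delta_bic` (winner minus runner-up, <= 0), and `fits`.
#' @export
select_model <- function(dataset, model_space, n_starts = 5, seed = 1,
                         bounds = NULL, cues = NULL) {
  if (length(model_space) < 2L) stop("model_space needs at least two models")
  fits <- lapply(model_space, function(mid)
    fit_mle(mid, dataset, bounds = bounds[[mid]], n_starts = n_starts,
            seed = derive_seed(seed, match(mid, model_ids())), cues = cues))
  names(fits) <- model_space
  bics <- vapply(fits, function(f) bic(f$loglik, f$k, f$n_obs), 0)
  ks <- vapply(fits, function(f) f$k, 0L)
  ord <- order(bics, ks, seq_along(model_space))
  winner <- model_space[ord[1L]]
  delta <- bics[ord[1L]] - bics[ord[2L]]
  structure(list(winner = winner, bic = bics, delta_bic = unname(delta),
                 fits = fits),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> winner:", x$winner,
      sprintf("(dBIC vs runner-up: %.3f)\n", x$delta_bic))
  print(round(x$bic, 3))
  invisible(x)
}
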