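#' The candidate model space
#'
#' Five generative models of conditioned responding are supported, identified
#' by string ids:
#'
#' * `"rw"` -- Rescorla-Wagner: delta-rule weight learning with a constant
#'   learning rate `alpha`; response is the summed weight of presented cues.
#' * `"krw"` -- Kalman Rescorla-Wagner: Bayesian weight learning with a full
#'   weight covariance (parameters `w0_var`, `q_diffusion`, `r_noise_var`),
#'   which supports retrospective revaluation such as backward blocking.
#' * `"rwph_v"`, `"rwph_alpha"`, `"rwph_valpha"` -- hybrid
#'   Rescorla-Wagner/Pearce-Hall: weights learned with dynamic per-cue
#'   associabilities (parameters `kappa`, `eta`, `alpha0`), emitting as the
#'   response the weights, the associabilities, or their `omega`-weighted
#'   mixture, respectively.
#'
#' All models add homoscedastic Gaussian observation noise with standard
#' deviation `sigma_obs` to the mean response. The US is coded 0/1 and the
#' asymptote `lambda` is fixed at 1.
#'
#' @param model_id one of the ids above.
#' @return `model_info()` returns a list describing the model: `dyn_params`
#'   (names of the dynamics parameters), `lower`/`upper` (their default
#'   fitting bounds), `log_scale` (which are searched on log10 scale),
#'   `k` (number of fitted parameters, including `sigma_obs`), and `mapping`.
#' @examples
#' model_info("rw")$k            # 2: alpha and sigma_obs
#' model_ids()
#' @export
model_info <- function(model_id) {
  info <- switch(model_id,
    rw = list(
      dyn_params = "alpha", lower = 0, upper = 1, log_scale = FALSE,
      k = 2L, mapping = "V"),
    krw = list(
      dyn_params = c("w0_var", "q_diffusion", "r_noise_var"),
      lower = rep(1e-4, 3), upper = rep(10, 3), log_scale = rep(TRUE, 3),
      k = 4L, mapping = "V"),
    rwph_v = list(
      dyn_params = c("kappa", "eta", "alpha0"),
      lower = rep(0, 3), upper = rep(1, 3), log_scale = rep(FALSE, 3),
      k = 4L, mapping = "V", faces = list(c(eta = 0))),
    rwph_alpha = list(
      dyn_params = c("kappa", "eta", "alpha0"),
      lower = rep(0, 3), upper = rep(1, 3), log_scale = rep(FALSE, 3),
      k = 4L, mapping = "alpha", faces = list(c(eta = 0))),
    rwph_valpha = list(
      dyn_params = c("kappa", "eta", "alpha0", "omega"),
      lower = rep(0, 4), upper = rep(1, 4), log_scale = rep(FALSE, 4),
      k = 5L, mapping = "V_plus_alpha",
      faces = list(c(eta = 0), c(omega = 0), c(omega = 1))),
    stop("unknown model_id: ", model_id)
  )
  info$id <- model_id
  names(info$lower) <- names(info$upper) <- info$dyn_params
  info
}

#' @rdname model_info
#' @export
model_ids <- function() c("rw", "krw", "rwph_v", "rwph_alpha", "rwph_valpha")

#' Encode an experiment realization as a stimulus matrix
#'
#' Maps each trial's presented stimulus to a binary row over the elemental
#' cues (a compound has a 1 for each of its members) and copies the outcome
#' vector. `decode_stimuli()` inverts the encoding back to presentable
#' labels.
#'
#' @param realization an `experiment_realization` (or any data frame with
#'   `stimulus` and `outcome` columns).
#' @param cues the [cue_set()] the stimuli are drawn from.
#' @return list with `X` (n x n_elements binary matrix) and `r` (0/1 outcome
#'   vector).
#' @export
encode_stimuli <- function(realization, cues) {
  memb <- cue_membership(cues)
  stim <- realization$stimulus
  bad <- setdiff(unique(stim), rownames(memb))
  if (length(bad))
    stop("unknown stimulus label(s): ", paste(bad, collapse = ", "))
  X <- memb[stim, , drop = FALSE]
  rownames(X) <- NULL
  list(X = X, r = as.numeric(realization$outcome))
}

#' @param X binary stimulus matrix with one row per trial.
#' @rdname encode_stimuli
#' @export
decode_stimuli <- function(X, cues) {
  memb <- cue_membership(cues)
  key <- apply(memb, 1, paste0, collapse = "")
  got <- apply(X, 1, paste0, collapse = "")
  idx <- match(got, key)
  if (anyNA(idx)) stop("row(s) do not correspond to a presentable stimulus")
  rownames(memb)[idx]
}

#' Single-trial Rescorla-Wagner update
#'
#' The delta rule: prediction error `delta = lambda * r - x %*% w`, and for
#' every cue `w' = w + alpha * delta * x`, so only presented cues change.
#'
#' @param w weight vector (one entry per elemental cue).
#' @param x binary stimulus row.
#' @param r outcome (0/1).
#' @param alpha learning rate in `[0, 1]`.
#' @param lambda US asymptote (fixed at 1 in all scenarios).
#' @return list with the updated weights `w` and the prediction error `delta`.
#' @examples
#' rw_step(c(A = 0), c(A = 1), r = 1, alpha = 0.2)  # delta = 1, w = 0.2
#' @export
rw_step <- function(w, x, r, alpha, lambda = 1) {
  stopifnot(length(w) == length(x))
  delta <- lambda * r - sum(x * w)
  list(w = w + alpha * delta * x, delta = delta)
}

#' Single-trial Kalman Rescorla-Wagner update
#'
#' Weights carry a Gaussian belief `N(w, Sigma)`. Each trial the belief first
#' diffuses (`Sigma + q I`), then conditions on the observed outcome through
#' the scalar measurement `x' w` with noise variance `r_noise_var`:
#' `gain = Sigma x / (x' Sigma x + r_noise_var)`,
#' `w' = w + gain (r - x' w)`, `Sigma' = Sigma - gain x' Sigma`
#' (re-symmetrized). The off-diagonal covariance learned on compound trials
#' is what produces backward blocking.
#'
#' @param w weight mean vector.
#' @param Sigma weight covariance (symmetric PSD).
#' @param x binary stimulus row.
#' @param r outcome (0/1).
#' @param q_diffusion per-trial weight-drift variance (>= 0).
#' @param r_noise_var outcome noise variance (> 0).
#' @return list with `w`, `Sigma`, `gain`, `delta`.
#' @export
krw_step <- function(w, Sigma, x, r, q_diffusion, r_noise_var) {
  Sigma <- as.matrix(Sigma)
  stopifnot(length(w) == length(x), nrow(Sigma) == length(w))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("Sigma is not positive semidefinite")
  Sigma <- Sigma + diag(q_diffusion, length(w))
  Sx <- drop(Sigma %*% x)
  denom <- sum(x * Sx) + r_noise_var
  gain <- Sx / denom
  delta <- r - sum(x * w)
  w2 <- w + gain * delta
  S2 <- Sigma - tcrossprod(gain, Sx)
  S2 <- (S2 + t(S2)) / 2
  list(w = w2, Sigma = S2, gain = gain, delta = delta)
}

#' Single-trial hybrid Rescorla-Wagner/Pearce-Hall update
#'
#' Each cue keeps a dynamic learning rate (associability). With prediction
#' error `delta = r - x' V`, presented cues update as
#' `V' = V + kappa * assoc * delta` and
#' `assoc' = eta * |delta| + (1 - eta) * assoc`; absent cues are unchanged.
#' With `eta = 0` the associabilities stay at their initial value and the
#' update reduces to Rescorla-Wagner with rate `kappa * alpha0` (the models
#' are nested).
#'
#' @param V weight vector.
#' @param assoc associability vector in `[0, 1]`.
#' @param x binary stimulus row.
#' @param r outcome (0/1).
#' @param kappa learning-rate scale in `[0, 1]`.
#' @param eta associability update rate in `[0, 1]`.
#' @return list with `V`, `assoc`, `delta`.
#' @export
rwph_step <- function(V, assoc, x, r, kappa, eta) {
  stopifnot(length(V) == length(x), length(assoc) == length(x))
  delta <- r - sum(x * V)
  pres <- x > 0
  V2 <- V
  a2 <- assoc
  V2[pres] <- V[pres] + kappa * assoc[pres] * delta
  a2[pres] <- eta * abs(delta) + (1 - eta) * assoc[pres]
  list(V = V2, assoc = a2, delta = delta)
}

#' Emit a conditioned response from latent model state
#'
#' The mean response to the presented stimulus `x` is `x' V` (mapping `"V"`),
#' `x' assoc` (mapping `"alpha"`), or the mixture
#' `(1 - omega) * x' V + omega * x' assoc` (mapping `"V_plus_alpha"`);
#' Gaussian observation noise with s.d. `sigma_obs` is added using the
#' current RNG state.
#'
#' @param V weight vector at the current trial (pre-outcome).
#' @param x binary stimulus row.
#' @param sigma_obs observation noise s.d. (>= 0; 0 gives the mean exactly).
#' @param mapping response mapping.
#' @param assoc associability vector (required for the `alpha` mappings).
#' @param omega mixture weight in `[0, 1]` (mapping `"V_plus_alpha"`).
#' @return the conditioned response `CR` (numeric scalar).
#' @export
emit_response <- function(V, x, sigma_obs,
                          mapping = c("V", "alpha", "V_plus_alpha"),
                          assoc = NULL, omega = 0) {
  mapping <- match.arg(mapping)
  m <- switch(mapping,
    V = sum(x * V),
    alpha = sum(x * assoc),
    V_plus_alpha = (1 - omega) * sum(x * V) + omega * sum(x * assoc))
  if (sigma_obs > 0) m + rnorm(1, 0, sigma_obs) else m
}

# required dynamics parameters with defaults filled in (w0 etc.);
# sigma_obs is only needed by callers that simulate or score responses
complete_params <- function(model_id, params) {
  defaults <- switch(model_id,
    rw = list(alpha = NULL, w0 = 0, lambda_us = 1, sigma_obs = NA_real_),
    krw = list(w0_mean = 0, w0_var = NULL, q_diffusion = NULL,
               r_noise_var = NULL, sigma_obs = NA_real_),
    rwph_v = ,
    rwph_alpha = list(kappa = NULL, eta = NULL, alpha0 = NULL, w0 = 0,
                      sigma_obs = NA_real_),
    rwph_valpha = list(kappa = NULL, eta = NULL, alpha0 = NULL, omega = NULL,
                       w0 = 0, sigma_obs = NA_real_),
    stop("unknown model_id: ", model_id))
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  missing <- names(defaults)[vapply(defaults, is.null, TRUE)]
  if (length(missing))
    stop("missing parameter(s) for ", model_id, ": ",
         paste(missing, collapse = ", "))
  defaults
}

# Mean responses (and optional latent traces) for a whole realization; the
# fast path behind simulation and likelihood evaluation.
model_mean_responses <- function(model_id, params, X, r, latents = FALSE) {
  p <- complete_params(model_id, params)
  if (model_id == "rw") {
    f <- rw_filter_cpp(X, r, p$alpha, p$w0, p$lambda_us)
    m <- f$m
  } else if (model_id == "krw") {
    f <- krw_filter_cpp(X, r, p$w0_mean, p$w0_var, p$q_diffusion, p$r_noise_var)
    m <- f$m
  } else {
    f <- rwph_filter_cpp(X, r, p$kappa, p$eta, p$alpha0, p$w0)
    m <- switch(model_info(model_id)$mapping,
                V = f$mV, alpha = f$mA,
                V_plus_alpha = (1 - p$omega) * f$mV + p$omega * f$mA)
  }
  if (latents) list(m = m, trace = f) else list(m = m)
}

#' Simulate a complete conditioning dataset
#'
#' Samples an experiment realization from the design, runs the chosen model's
#' learning recursion trial by trial, and emits one conditioned response per
#' trial from the pre-outcome prediction (the model responds to the CS before
#' the US arrives). Fully reproducible from `seed`.
#'
#' @param design a valid `cond_design` (or an unrolled
#'   `contingency_schedule`).
#' @param model_id a model id (see [model_info()]).
#' @param params named list of generative parameter values, including
#'   `sigma_obs`.
#' @param seed integer seed.
#' @param latents if `TRUE`, attach the per-trial latent trace (weights,
#'   prediction errors, associabilities/covariances) as attribute `"latents"`.
#' @return A `cond_dataset`: data frame `trial, stimulus, outcome, response`
#'   with the cue set, model id and parameters in attributes.
#' @examples
#' d <- stagewise_design(cue_set("A"), list(design_stage(5, c(A = 1), c(A = 1))))
#' simulate_dataset(d, "rw", list(alpha = 0.2, sigma_obs = 0), seed = 1)$response
#' @export
simulate_dataset <- function(design, model_id, params, seed, latents = FALSE) {
  info <- model_info(model_id)   # validates the id
  schedule <- if (inherits(design, "contingency_schedule")) design
              else unroll_schedule(design)
  realization <- sample_realization(schedule, derive_seed(seed, 1L))
  enc <- encode_stimuli(realization, schedule$cues)
  p <- complete_params(model_id, params)
  if (!is.finite(p$sigma_obs) || p$sigma_obs < 0)
    stop("sigma_obs must be a finite non-negative number")
  mr <- model_mean_responses(model_id, p, enc$X, enc$r, latents = latents)
  cr <- with_seed(derive_seed(seed, 2L), {
    if (p$sigma_obs > 0) mr$m + rnorm(length(mr$m), 0, p$sigma_obs) else mr$m
  })
  out <- data.frame(trial = realization$trial,
                    stimulus = realization$stimulus,
                    outcome = realization$outcome,
                    response = cr, stringsAsFactors = FALSE)
  attr(out, "cues") <- schedule$cues
  attr(out, "model_id") <- model_id
  attr(out, "params") <- p
  if (latents) attr(out, "latents") <- mr$trace
  class(out) <- c("cond_dataset", "data.frame")
  out
}

#' Gaussian log-likelihood of a dataset under a model
#'
#' Sum over trials of the Gaussian log-density of the observed conditioned
#' response around the model's pre-outcome mean response, with standard
#' deviation `sigma_obs`. Deterministic.
#'
#' @param model_id a model id.
#' @param params named list including `sigma_obs` (> 0).
#' @param dataset a `cond_dataset` (needs columns `stimulus`, `outcome`,
#'   `response` and a `cues` attribute, or pass `cues`).
#' @param cues optional [cue_set()] overriding the dataset attribute.
#' @return log-likelihood (numeric scalar).
#' @export
log_likelihood <- function(model_id, params, dataset, cues = NULL) {
  if (is.null(cues)) cues <- attr(dataset, "cues")
  if (is.null(cues)) stop("dataset carries no cue_set; pass `cues`")
  if (nrow(dataset) < 1L) stop("dataset has no trials")
  p <- complete_params(model_id, params)
  if (!isTRUE(is.finite(p$sigma_obs) && p$sigma_obs > 0))
    stop("sigma_obs must be > 0")
  enc <- encode_stimuli(dataset, cues)
  m <- model_mean_responses(model_id, p, enc$X, enc$r)$m
  sum(dnorm(dataset$response, mean = m, sd = p$sigma_obs, log = TRUE))
}

#' Read or write a simulated dataset as CSV
#'
#' Datasets are stored as plain CSV with columns
#' `trial,stimulus,outcome,response` (1-based trial numbers). The cue set is
#' not stored; supply it again when reading.
#'
#' @param dataset a `cond_dataset`.
#' @param path file path.
#' @param cues the [cue_set()] to re-attach on read.
#' @return `write_dataset_csv` returns `path` invisibly; `read_dataset_csv`
#'   returns a `cond_dataset`.
#' @export
write_dataset_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path, cues) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  attr(out, "cues") <- cues
  class(out) <- c("cond_dataset", "data.frame")
  out
}
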