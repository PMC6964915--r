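#' Stage-wise parameterization of a conditioning experiment
#'
#' In the stage-wise parameterization the experiment is divided into
#' contiguous blocks of trials (stages). Within a stage every trial is
#' generated by the same Markov chain: a presentable stimulus is drawn with
#' probability `P(CS)` and the outcome (US) follows with probability
#' `P(US|CS)`. Classical designs -- blocking, backward blocking, reversal
#' learning, conditioned inhibition -- are special cases.
#'
#' @param cues a [cue_set()].
#' @param stages list of stages, each created by [design_stage()].
#' @return An object of class `stagewise_design` (also `cond_design`).
#' @seealso [periodic_design()], [validate_design()], [unroll_schedule()]
#' @examples
#' cs <- cue_set("A")
#' d <- stagewise_design(cs, list(
#'   design_stage(10, cue_probs = c(A = 1), outcome_probs = c(A = 0.5)),
#'   design_stage(10, cue_probs = c(A = 1), outcome_probs = c(A = 0))
#' ))
#' @export
stagewise_design <- function(cues, stages) {
  stopifnot(inherits(cues, "cue_set"))
  stages <- lapply(stages, function(s) {
    s$cue_probs <- align_probs(s$cue_probs, cues$presentable, "cue_probs")
    s$outcome_probs <- align_probs(s$outcome_probs, cues$presentable, "outcome_probs")
    s
  })
  structure(list(cues = cues, stages = stages),
            class = c("stagewise_design", "cond_design"))
}

#' @param n_trials number of trials in the stage (positive integer).
#' @param cue_probs named numeric, presentation probability per presentable
#'   stimulus; must sum to 1. Omitted stimuli get probability 0.
#' @param outcome_probs named numeric, `P(US|CS)` per presentable stimulus.
#' @rdname stagewise_design
#' @export
design_stage <- function(n_trials, cue_probs, outcome_probs) {
  list(n_trials = n_trials, cue_probs = cue_probs, outcome_probs = outcome_probs)
}

#' Periodic parameterization of a conditioning experiment
#'
#' Contingencies follow a square wave: every transition probability of the
#' trial-generating Markov chain alternates between two levels `P1` and `P2`
#' with a common half-period `T`, expressed as a fraction of the total number
#' of trials. Trial `t` (0-based) uses level `P1` when
#' `floor(t / ceiling(T * n_trials))` is even and `P2` otherwise, so `T = 1`
#' yields a constant `P1` schedule and `T = 0.5` a single mid-experiment
#' switch.
#'
#' @param cues a [cue_set()].
#' @param n_trials total number of trials.
#' @param cue_p1,cue_p2 named numeric, the two levels of the stimulus
#'   presentation probabilities; each must sum to 1 across stimuli.
#' @param outcome_p1,outcome_p2 named numeric, the two levels of `P(US|CS)`.
#' @param half_period the half-period `T` in `(0, 1]`, as a fraction of
#'   `n_trials`.
#' @return An object of class `periodic_design` (also `cond_design`).
#' @examples
#' # acquisition (50% reinforcement) followed by extinction
#' d <- periodic_design(cue_set("A"), n_trials = 160,
#'                      cue_p1 = c(A = 1), cue_p2 = c(A = 1),
#'                      outcome_p1 = c(A = 0.5), outcome_p2 = c(A = 0),
#'                      half_period = 0.5)
#' @export
periodic_design <- function(cues, n_trials, cue_p1, cue_p2,
                            outcome_p1, outcome_p2, half_period) {
  stopifnot(inherits(cues, "cue_set"))
  p <- cues$presentable
  structure(
    list(cues = cues, n_trials = n_trials,
         cue_p1 = align_probs(cue_p1, p, "cue_p1"),
         cue_p2 = align_probs(cue_p2, p, "cue_p2"),
         outcome_p1 = align_probs(outcome_p1, p, "outcome_p1"),
         outcome_p2 = align_probs(outcome_p2, p, "outcome_p2"),
         half_period = half_period),
    class = c("periodic_design", "cond_design")
  )
}

align_probs <- function(x, labels, what) {
  if (is.null(names(x))) {
    if (length(x) != length(labels))
      stop(what, " must be named or match the number of presentable stimuli")
    names(x) <- labels
  }
  if (!all(names(x) %in% labels))
    stop(what, " has unknown stimulus labels: ",
         paste(setdiff(names(x), labels), collapse = ", "))
  out <- setNames(numeric(length(labels)), labels)
  out[names(x)] <- as.numeric(x)
  out
}

#' @export
print.cond_design <- function(x, ...) {
  if (inherits(x, "stagewise_design")) {
    cat("<stagewise_design>", length(x$stages), "stages,",
        total_trials(x), "trials,",
        length(x$cues$presentable), "presentable stimuli\n")
    for (i in seq_along(x$stages)) {
      s <- x$stages[[i]]
      cat(sprintf("  stage %d (%d trials): P(CS)=[%s]  P(US|CS)=[%s]\n", i,
                  s$n_trials,
                  paste(sprintf("%s:%.2f", names(s$cue_probs), s$cue_probs), collapse = " "),
                  paste(sprintf("%s:%.2f", names(s$outcome_probs), s$outcome_probs), collapse = " ")))
    }
  } else {
    cat("<periodic_design>", x$n_trials, "trials, half-period",
        x$half_period, "\n")
    cat(sprintf("  P(CS):    P1=[%s] P2=[%s]\n",
                paste(sprintf("%s:%.2f", names(x$cue_p1), x$cue_p1), collapse = " "),
                paste(sprintf("%s:%.2f", names(x$cue_p2), x$cue_p2), collapse = " ")))
    cat(sprintf("  P(US|CS): P1=[%s] P2=[%s]\n",
                paste(sprintf("%s:%.2f", names(x$outcome_p1), x$outcome_p1), collapse = " "),
                paste(sprintf("%s:%.2f", names(x$outcome_p2), x$outcome_p2), collapse = " ")))
  }
  invisible(x)
}

#' Total number of trials of a design
#' @param design a `cond_design`.
#' @return integer trial count.
#' @export
total_trials <- function(design) {
  if (inherits(design, "stagewise_design"))
    sum(vapply(design$stages, function(s) as.numeric(s$n_trials), 0))
  else design$n_trials
}

#' Check the probabilistic constraints of a design
#'
#' Verifies that every transition probability lies in `[0, 1]`, that the
#' stimulus-presentation probabilities leaving the trial-start state sum to 1
#' (the Markov-chain simplex constraint), that trial counts are positive
#' integers, and (periodic designs) that the half-period lies in `(0, 1]`.
#' Violations are reported, never raised.
#'
#' @param design a `cond_design`.
#' @return list with `ok` (logical) and `violations` (character vector,
#'   empty when the design passes).
#' @examples
#' d <- stagewise_design(cue_set("A"),
#'   list(design_stage(5, c(A = 1), c(A = 0.5))))
#' validate_design(d)$ok
#' @export
validate_design <- function(design) {
  v <- character()
  tol <- 1e-9
  chk_bounds <- function(p, what) {
    if (any(p < -tol | p > 1 + tol))
      sprintf("%s outside [0,1]: [%s]", what,
              paste(signif(p, 4), collapse = ", "))
    else character()
  }
  chk_simplex <- function(p, what) {
    if (abs(sum(p) - 1) > 1e-9)
      sprintf("%s must sum to 1 (sum = %.6g)", what, sum(p))
    else character()
  }
  if (inherits(design, "stagewise_design")) {
    if (length(design$stages) < 1L) v <- c(v, "design has no stages")
    for (i in seq_along(design$stages)) {
      s <- design$stages[[i]]
      if (!is.numeric(s$n_trials) || s$n_trials < 1 ||
          s$n_trials != round(s$n_trials))
        v <- c(v, sprintf("stage %d: n_trials must be a positive integer", i))
      v <- c(v, chk_bounds(s$cue_probs, sprintf("stage %d cue_probs", i)),
             chk_bounds(s$outcome_probs, sprintf("stage %d outcome_probs", i)),
             chk_simplex(s$cue_probs, sprintf("stage %d cue_probs", i)))
    }
  } else if (inherits(design, "periodic_design")) {
    if (!is.numeric(design$n_trials) || design$n_trials < 1 ||
        design$n_trials != round(design$n_trials))
      v <- c(v, "n_trials must be a positive integer")
    v <- c(v, chk_bounds(design$cue_p1, "cue_p1"),
           chk_bounds(design$cue_p2, "cue_p2"),
           chk_bounds(design$outcome_p1, "outcome_p1"),
           chk_bounds(design$outcome_p2, "outcome_p2"),
           chk_simplex(design$cue_p1, "cue_p1"),
           chk_simplex(design$cue_p2, "cue_p2"))
    if (!is.numeric(design$half_period) || design$half_period <= 0 ||
        design$half_period > 1)
      v <- c(v, "half_period must lie in (0, 1]")
  } else {
    v <- c(v, "not a cond_design object")
  }
  list(ok = length(v) == 0L, violations = v)
}

stop_if_invalid <- function(design) {
  val <- validate_design(design)
  if (!val$ok)
    stop("invalid design: ", paste(val$violations, collapse = "; "),
         call. = FALSE)
  invisible(design)
}

#' Unroll a design into per-trial contingencies
#'
#' Expands a stage-wise or periodic design into its explicit per-trial form:
#' one row of stimulus-presentation probabilities and one row of conditional
#' outcome probabilities per trial. For periodic designs, trial `t` (0-based)
#' takes level `P1` when `floor(t / ceiling(T * n_trials))` is even, `P2`
#' otherwise.
#'
#' @param design a valid `cond_design`.
#' @return A `contingency_schedule`: list with `cues`, `n_trials`, and the
#'   `n_trials x n_stimuli` matrices `cue_probs` and `outcome_probs`.
#' @examples
#' d <- periodic_design(cue_set("A"), 8, c(A = 1), c(A = 1),
#'                      c(A = 0.5), c(A = 0), half_period = 0.25)
#' unroll_schedule(d)$outcome_probs[, "A"]
#' @export
unroll_schedule <- function(design) {
  stop_if_invalid(design)
  labs <- design$cues$presentable
  n <- total_trials(design)
  if (inherits(design, "stagewise_design")) {
    cue <- do.call(rbind, lapply(design$stages, function(s)
      matrix(s$cue_probs, nrow = s$n_trials, ncol = length(labs), byrow = TRUE)))
    out <- do.call(rbind, lapply(design$stages, function(s)
      matrix(s$outcome_probs, nrow = s$n_trials, ncol = length(labs), byrow = TRUE)))
  } else {
    block <- ceiling(design$half_period * n)
    t0 <- seq_len(n) - 1L                 # 0-based trial index
    use_p1 <- (t0 %/% block) %% 2L == 0L
    cue <- matrix(NA_real_, n, length(labs))
    out <- matrix(NA_real_, n, length(labs))
    cue[use_p1, ] <- matrix(design$cue_p1, sum(use_p1), length(labs), byrow = TRUE)
    cue[!use_p1, ] <- matrix(design$cue_p2, sum(!use_p1), length(labs), byrow = TRUE)
    out[use_p1, ] <- matrix(design$outcome_p1, sum(use_p1), length(labs), byrow = TRUE)
    out[!use_p1, ] <- matrix(design$outcome_p2, sum(!use_p1), length(labs), byrow = TRUE)
  }
  colnames(cue) <- colnames(out) <- labs
  structure(list(cues = design$cues, n_trials = as.integer(n),
                 cue_probs = cue, outcome_probs = out),
            class = "contingency_schedule")
}

#' @export
print.contingency_schedule <- function(x, ...) {
  cat("<contingency_schedule>", x$n_trials, "trials x",
      ncol(x$cue_probs), "stimuli\n")
  invisible(x)
}

#' Sample an experiment realization from a contingency schedule
#'
#' Draws, for every trial, a presentable stimulus from that trial's cue
#' probabilities and then a binary outcome (US) with the stimulus's
#' conditional outcome probability. Identical seeds give identical
#' realizations.
#'
#' @param schedule a [unroll_schedule()] result (or a `cond_design`, which is
#'   unrolled first).
#' @param seed integer seed.
#' @return An `experiment_realization`: data frame with columns `trial`
#'   (1-based), `stimulus` (label) and `outcome` (0/1); the cue set is kept in
#'   the `cues` attribute.
#' @examples
#' d <- stagewise_design(cue_set("A"), list(design_stage(5, c(A = 1), c(A = 1))))
#' sample_realization(unroll_schedule(d), seed = 1)
#' @export
sample_realization <- function(schedule, seed) {
  if (inherits(schedule, "cond_design")) schedule <- unroll_schedule(schedule)
  stopifnot(inherits(schedule, "contingency_schedule"))
  labs <- colnames(schedule$cue_probs)
  n <- schedule$n_trials
  with_seed(seed, {
    idx <- integer(n)
    for (t in seq_len(n))
      idx[t] <- sample.int(length(labs), 1L, prob = schedule$cue_probs[t, ])
    p_us <- schedule$outcome_probs[cbind(seq_len(n), idx)]
    outcome <- as.integer(runif(n) < p_us)
    out <- data.frame(trial = seq_len(n), stimulus = labs[idx],
                      outcome = outcome, stringsAsFactors = FALSE)
    attr(out, "cues") <- schedule$cues
    class(out) <- c("experiment_realization", "data.frame")
    out
  })
}

#' Read or write an experiment realization as CSV
#'
#' Realizations are stored as plain CSV with columns `trial,stimulus,outcome`
#' (1-based trial numbers).
#'
#' @param realization an `experiment_realization` (or dataset data frame).
#' @param path file path.
#' @return `write_realization_csv` returns `path` invisibly;
#'   `read_realization_csv` returns a data frame.
#' @export
write_realization_csv <- function(realization, path) {
  write.csv(as.data.frame(realization), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_realization_csv
#' @export
read_realization_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Serialize a design to a YAML document (and back)
#'
#' @param design a `cond_design`.
#' @param path file path; `.yaml` is conventional.
#' @return `write_design_yaml` returns `path` invisibly; `read_design_yaml`
#'   reconstructs the design object.
#' @export
write_design_yaml <- function(design, path) {
  cs <- design$cues
  doc <- list(
    parameterization = if (inherits(design, "stagewise_design")) "stage-wise" else "periodic",
    cues = as.list(cs$elements),
    compounds = unname(lapply(cs$compounds, as.list))
  )
  if (inherits(design, "stagewise_design")) {
    doc$stages <- lapply(design$stages, function(s) list(
      n_trials = s$n_trials,
      cue_probs = as.list(s$cue_probs),
      outcome_probs = as.list(s$outcome_probs)))
  } else {
    doc$n_trials <- design$n_trials
    doc$periodic <- list(
      half_period = design$half_period,
      cue_p1 = as.list(design$cue_p1), cue_p2 = as.list(design$cue_p2),
      outcome_p1 = as.list(design$outcome_p1),
      outcome_p2 = as.list(design$outcome_p2))
  }
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

# undo the tiny simplex drift YAML's decimal rendering can introduce
renorm_simplex <- function(p, tol = 1e-6) {
  s <- sum(p)
  if (s > 0 && abs(s - 1) <= tol) p / s else p
}

#' @rdname write_design_yaml
#' @export
read_design_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  cs <- cue_set(unlist(doc$cues),
                compounds = lapply(doc$compounds, unlist))
  if (identical(doc$parameterization, "stage-wise")) {
    stagewise_design(cs, lapply(doc$stages, function(s)
      design_stage(s$n_trials, renorm_simplex(unlist(s$cue_probs)),
                   unlist(s$outcome_probs))))
  } else {
    p <- doc$periodic
    periodic_design(cs, doc$n_trials,
                    renorm_simplex(unlist(p$cue_p1)),
                    renorm_simplex(unlist(p$cue_p2)),
                    unlist(p$outcome_p1), unlist(p$outcome_p2),
                    p$half_period)
  }
}
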