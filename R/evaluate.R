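#' Common-language effect size (probability of superiority)
#'
#' Over all cross pairs of two utility samples, the fraction of pairs in
#' which the first exceeds the second, with ties counted as 1/2. A value of
#' 0.5 indicates designs of equal quality. Samples are treated as
#' independent (unpaired), matching independently simulated experiments from
#' two designs.
#'
#' @param u_x,u_y non-empty numeric utility vectors.
#' @return the CLES, in `[0, 1]`.
#' @examples
#' cles(c(1, 2), c(1, 3))  # 0.375
#' @export
cles <- function(u_x, u_y) {
  if (length(u_x) == 0L || length(u_y) == 0L) stop("empty utility vector")
  cmp <- outer(u_x, u_y, ">") + 0.5 * outer(u_x, u_y, "==")
  mean(cmp)
}

#' Percentile-bootstrap confidence interval for a two-sample statistic
#'
#' Resamples the two vectors independently with replacement, recomputes the
#' statistic, and returns the percentile interval (default 95% from 1000
#' bootstrap samples). Deterministic given the seed.
#'
#' @param u_x,u_y numeric vectors.
#' @param statistic a function of two vectors (default [cles()]).
#' @param n_boot number of bootstrap samples (>= 100).
#' @param level confidence level.
#' @param seed integer seed.
#' @return named vector `c(lo, hi)`.
#' @export
percentile_bootstrap_ci <- function(u_x, u_y, statistic = cles,
                                    n_boot = 1000, level = 0.95, seed = 1) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      statistic(u_x[sample.int(length(u_x), replace = TRUE)],
                u_y[sample.int(length(u_y), replace = TRUE)])
    }, 0)
  })
  a <- (1 - level) / 2
  out <- quantile(stats, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = out[1], hi = out[2])
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Beta-quantile (exact) interval for a binomial proportion; the lower bound
#' is 0 when there are no successes and the upper bound 1 when there are no
#' failures.
#'
#' @param successes number of successes (0 to `n`).
#' @param n number of trials (>= 1).
#' @param level confidence level.
#' @return named vector `c(lo, hi)`.
#' @examples
#' clopper_pearson(512, 512)  # lower bound ~0.9928
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("successes must be in [0, n]")
  a <- (1 - level) / 2
  lo <- if (successes == 0) 0 else qbeta(a, successes, n - successes + 1)
  hi <- if (successes == n) 1 else qbeta(1 - a, successes + 1, n - successes)
  c(lo = lo, hi = hi)
}

#' Odds ratio with Woolf confidence interval (Haldane-Anscombe correction)
#'
#' Builds the 2x2 correct/incorrect-by-design table, computes the odds ratio
#' of design A being correct relative to design B, and the log-scale Woolf
#' interval `exp(log(OR) +/- z * sqrt(sum(1/cell)))`. When any cell is zero
#' (or when `always_correct = TRUE`), 0.5 is added to all four cells first,
#' keeping the estimate finite. `OR = 1` indicates designs of equal expected
#' utility.
#'
#' @param correct_a,n_a successes and total for design A.
#' @param correct_b,n_b successes and total for design B.
#' @param level confidence level.
#' @param always_correct add 0.5 to every cell regardless of zeros.
#' @return named vector `c(or, lo, hi)`.
#' @examples
#' odds_ratio_woolf(971, 1024, 611, 1024)  # OR ~ 12.4
#' @export
odds_ratio_woolf <- function(correct_a, n_a, correct_b, n_b, level = 0.95,
                             always_correct = FALSE) {
  if (n_a < 1 || n_b < 1) stop("both designs need at least one simulation")
  if (correct_a < 0 || correct_a > n_a || correct_b < 0 || correct_b > n_b)
    stop("invalid counts")
  cells <- c(a = correct_a, b = n_a - correct_a,
             c = correct_b, d = n_b - correct_b)
  if (always_correct || any(cells == 0)) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * z * se)
  c(or = unname(or), lo = ci[1], hi = ci[2])
}

#' Confusion matrix and model recovery rates
#'
#' Cross-tabulates ground-truth models (rows) against selected models
#' (columns) over simulated experiments. The recovery rate of a model is the
#' diagonal count divided by its row total.
#'
#' @param truth,selected character vectors of model ids (equal length).
#' @param model_space the candidate model ids fixing row/column order.
#' @return list with `matrix` (counts), `recovery` (per-model rates), and
#'   `accuracy` (overall fraction correct).
#' @export
confusion_matrix <- function(truth, selected, model_space) {
  if (length(truth) != length(selected)) stop("length mismatch")
  bad <- setdiff(unique(c(truth, selected)), model_space)
  if (length(bad)) stop("unknown model label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(truth, levels = model_space),
             factor(selected, levels = model_space))
  m <- unclass(m)
  dimnames(m) <- list(truth = model_space, selected = model_space)
  rs <- rowSums(m)
  recovery <- ifelse(rs > 0, diag(m) / rs, NA_real_)
  list(matrix = m, recovery = setNames(recovery, model_space),
       accuracy = sum(diag(m)) / sum(m))
}

#' Compare the utility distributions of evaluated designs
#'
#' Builds a pairwise comparison report from per-design evaluation results
#' ([expected_design_utility()] objects): CLES with percentile-bootstrap CIs
#' for every ordered pair and, for model-selection utilities, per-design
#' accuracies with Clopper-Pearson intervals, pairwise odds ratios
#' (Woolf/Haldane-Anscombe), and per-design confusion matrices.
#'
#' @param evaluations named list of `expected_utility` objects (names are
#'   design labels).
#' @param model_space candidate models (selection scenarios); taken from the
#'   first evaluation if omitted.
#' @param n_boot,level bootstrap samples and confidence level.
#' @param seed integer seed for the bootstrap.
#' @return A `comparison_report` list.
#' @export
compare_designs <- function(evaluations, model_space = NULL,
                            n_boot = 1000, level = 0.95, seed = 1) {
  stopifnot(length(evaluations) >= 2L, !is.null(names(evaluations)))
  labels <- names(evaluations)
  selection <- evaluations[[1L]]$analysis == "select"
  pairs <- list()
  for (a in labels) for (b in labels) {
    if (a == b) next
    ux <- evaluations[[a]]$utilities
    uy <- evaluations[[b]]$utilities
    entry <- list(
      cles = cles(ux, uy),
      cles_ci = percentile_bootstrap_ci(ux, uy, n_boot = n_boot,
                                        level = level, seed = seed))
    if (selection) {
      entry$odds_ratio <- odds_ratio_woolf(sum(ux), length(ux),
                                           sum(uy), length(uy), level = level)
    }
    pairs[[paste(a, "vs", b)]] <- entry
  }
  per_design <- lapply(evaluations, function(e) {
    out <- list(mean_utility = e$mean, se = e$se, n_sims = e$n_sims)
    if (selection) {
      out$accuracy <- mean(e$utilities)
      out$accuracy_ci <- clopper_pearson(sum(e$utilities), e$n_sims, level)
      if (is.null(model_space))
        model_space <- sort(unique(e$truth_models))
      ok <- !is.na(e$selected)
      out$confusion <- confusion_matrix(e$truth_models[ok], e$selected[ok],
                                        model_space)
    }
    out
  })
  structure(list(designs = per_design, pairs = pairs, level = level),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", length(x$designs), "designs\n")
  for (nm in names(x$designs)) {
    d <- x$designs[[nm]]
    if (!is.null(d$accuracy))
      cat(sprintf("  %s: accuracy %.3f [%.3f, %.3f] (n=%d)\n", nm, d$accuracy,
                  d$accuracy_ci["lo"], d$accuracy_ci["hi"], d$n_sims))
    else
      cat(sprintf("  %s: mean utility %.4f (SE %.4f, n=%d)\n", nm,
                  d$mean_utility, d$se, d$n_sims))
  }
  for (nm in names(x$pairs)) {
    p <- x$pairs[[nm]]
    cat(sprintf("  %s: CLES %.3f [%.3f, %.3f]", nm, p$cles,
                p$cles_ci["lo"], p$cles_ci["hi"]))
    if (!is.null(p$odds_ratio))
      cat(sprintf("  OR %.2f [%.2f, %.2f]", p$odds_ratio["or"],
                  p$odds_ratio["lo"], p$odds_ratio["hi"]))
    cat("\n")
  }
  invisible(x)
}
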