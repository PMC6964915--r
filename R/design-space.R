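#' Design spaces: mapping designs to and from optimization vectors
#'
#' A design space fixes the experiment structure (cue set, number of stages
#' and trials, parameterization) and declares the free design variables that
#' an optimizer may tune. Every free variable lives in `[0, 1]`, so the
#' optimizer sees a plain box; the simplex constraint on stimulus
#' probabilities (they must sum to 1) is enforced by construction through a
#' stick-breaking transform, never by rejection. For a cue set with `m`
#' presentable stimuli this yields, per stage, `m - 1` cue-probability
#' variables plus `m` outcome-probability variables; the periodic
#' parameterization has the two cue-probability simplices, the two
#' outcome-probability levels and the shared half-period `T`.
#'
#' The two-stage, three-stimulus space (blocking-type experiments) therefore
#' has 10 non-redundant variables, and the two-stage, two-stimulus space
#' (reversal-type experiments) has 6.
#'
#' @param parameterization `"stage-wise"` or `"periodic"`.
#' @param cues a [cue_set()].
#' @param stage_trials integer vector of per-stage trial counts (stage-wise).
#' @param n_trials total trial count (periodic).
#' @return A `design_space` with fields `dim`, `var_names` and the fixed
#'   structure.
#' @examples
#' sp <- design_space("stage-wise", cue_set(c("A", "B"), list(c("A", "B"))),
#'                    stage_trials = c(25, 25))
#' sp$dim  # 10
#' @export
design_space <- function(parameterization = c("stage-wise", "periodic"),
                         cues, stage_trials = NULL, n_trials = NULL) {
  parameterization <- match.arg(parameterization)
  stopifnot(inherits(cues, "cue_set"))
  m <- length(cues$presentable)
  labs <- cues$presentable
  if (parameterization == "stage-wise") {
    if (is.null(stage_trials) || length(stage_trials) < 1L)
      stop("stage-wise spaces need stage_trials")
    nm <- unlist(lapply(seq_along(stage_trials), function(i) {
      c(if (m > 1) sprintf("s%d_cue%d", i, seq_len(m - 1)),
        sprintf("s%d_us_%s", i, labs))
    }))
  } else {
    if (is.null(n_trials)) stop("periodic spaces need n_trials")
    nm <- c(if (m > 1) sprintf("cueP1_%d", seq_len(m - 1)),
            if (m > 1) sprintf("cueP2_%d", seq_len(m - 1)),
            sprintf("usP1_%s", labs), sprintf("usP2_%s", labs), "T")
  }
  structure(list(parameterization = parameterization, cues = cues,
                 stage_trials = stage_trials, n_trials = n_trials,
                 dim = length(nm), var_names = nm),
            class = "design_space")
}

#' @export
print.design_space <- function(x, ...) {
  cat("<design_space>", x$parameterization, "|", x$dim, "free variables\n")
  invisible(x)
}

# stick-breaking: v in [0,1]^(m-1)  ->  p on the m-simplex
stick_break <- function(v, m) {
  if (m == 1L) return(1)
  p <- numeric(m)
  rem <- 1
  for (i in seq_len(m - 1L)) {
    p[i] <- v[i] * rem
    rem <- rem - p[i]
  }
  p[m] <- max(rem, 0)
  p
}

# inverse stick-breaking (0/0 mapped to 0 so degenerate simplices round-trip)
stick_unbreak <- function(p) {
  m <- length(p)
  if (m == 1L) return(numeric(0))
  v <- numeric(m - 1L)
  rem <- 1
  for (i in seq_len(m - 1L)) {
    v[i] <- if (rem <= 0) 0 else min(max(p[i] / rem, 0), 1)
    rem <- rem - p[i]
  }
  v
}

#' Decode an optimization vector into a design
#'
#' `from_vector()` maps a point of the unit box `[0, 1]^d` to a valid design;
#' cue-probability coordinates pass through the stick-breaking transform so
#' the simplex constraint holds by construction. `to_vector()` is the inverse
#' for structurally matching designs; the round trip is the identity for
#' valid designs.
#'
#' @param space a [design_space()].
#' @param v numeric vector in `[0, 1]^d`.
#' @return `from_vector`: a `cond_design`; `to_vector`: a numeric vector of
#'   length `space$dim`.
#' @examples
#' sp <- design_space("periodic", cue_set("A"), n_trials = 160)
#' d <- from_vector(sp, c(0.5, 0, 0.5))   # P1=0.5, P2=0, T=0.5
#' all.equal(to_vector(sp, d), c(0.5, 0, 0.5), check.attributes = FALSE)
#' @export
from_vector <- function(space, v) {
  stopifnot(inherits(space, "design_space"))
  v <- as.numeric(v)
  if (length(v) != space$dim)
    stop("vector length ", length(v), " does not match space dimension ", space$dim)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("vector outside [0,1]^d")
  m <- length(space$cues$presentable)
  labs <- space$cues$presentable
  pos <- 0L
  take <- function(k) {
    out <- v[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  if (space$parameterization == "stage-wise") {
    stages <- lapply(space$stage_trials, function(nt) {
      cue <- setNames(stick_break(take(m - 1L), m), labs)
      us <- setNames(take(m), labs)
      design_stage(nt, cue, us)
    })
    stagewise_design(space$cues, stages)
  } else {
    c1 <- setNames(stick_break(take(m - 1L), m), labs)
    c2 <- setNames(stick_break(take(m - 1L), m), labs)
    u1 <- setNames(take(m), labs)
    u2 <- setNames(take(m), labs)
    tt <- max(take(1L), 1e-9)           # T must be strictly positive
    periodic_design(space$cues, space$n_trials, c1, c2, u1, u2, tt)
  }
}

#' @param design a `cond_design` structurally compatible with `space`.
#' @rdname from_vector
#' @export
to_vector <- function(space, design) {
  stopifnot(inherits(space, "design_space"))
  m <- length(space$cues$presentable)
  if (!identical(space$cues$presentable, design$cues$presentable))
    stop("design's cue set does not match the space")
  if (space$parameterization == "stage-wise") {
    if (!inherits(design, "stagewise_design") ||
        length(design$stages) != length(space$stage_trials))
      stop("design structure does not match the space")
    v <- unlist(lapply(design$stages, function(s)
      c(stick_unbreak(s$cue_probs), unname(s$outcome_probs))))
  } else {
    if (!inherits(design, "periodic_design"))
      stop("design structure does not match the space")
    v <- c(stick_unbreak(design$cue_p1), stick_unbreak(design$cue_p2),
           unname(design$outcome_p1), unname(design$outcome_p2),
           design$half_period)
  }
  setNames(as.numeric(v), space$var_names)
}
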