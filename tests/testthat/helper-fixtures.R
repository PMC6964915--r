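# Small builders shared across the test files. All fixtures are generated in
# code; nothing is read from disk.

single_cue_design <- function(n_trials, p_us) {
  stagewise_design(cue_set("A"),
                   list(design_stage(n_trials, c(A = 1), c(A = p_us))))
}

# reversal-rich single-cue schedule: frequent contingency switches make the
# learning rate well identified
switching_design <- function(n_trials = 200, p1 = 0.9, p2 = 0.1, T = 0.125) {
  periodic_design(cue_set("A"), n_trials,
                  cue_p1 = c(A = 1), cue_p2 = c(A = 1),
                  outcome_p1 = c(A = p1), outcome_p2 = c(A = p2),
                  half_period = T)
}

bb_cues <- function() cue_set(c("A", "B"), compounds = list(c("A", "B")))

# random stimulus matrix over two elements incl. compound rows
random_trials <- function(n, seed) {
  set.seed(seed)
  kind <- sample(1:3, n, replace = TRUE)
  X <- cbind(as.numeric(kind != 2L), as.numeric(kind != 1L))
  r <- as.numeric(runif(n) < 0.5)
  list(X = X, r = r)
}
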