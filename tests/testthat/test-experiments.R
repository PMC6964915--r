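test_that("validate_design passes reference designs and reports violations", {
  bb <- build_reference_design("backward_blocking")
  expect_true(validate_design(bb)$ok)

  cs <- cue_set(c("A", "B"))
  bad_simplex <- stagewise_design(cs, list(
    design_stage(10, c(A = 0.7, B = 0.7), c(A = 0.5, B = 0.5))))
  v <- validate_design(bad_simplex)
  expect_false(v$ok)
  expect_match(paste(v$violations, collapse = " "), "sum to 1")

  bad_bounds <- stagewise_design(cs, list(
    design_stage(10, c(A = 1, B = 0), c(A = -0.1, B = 0.5))))
  v <- validate_design(bad_bounds)
  expect_false(v$ok)
  expect_match(paste(v$violations, collapse = " "), "outside \\[0,1\\]")

  zero_stage <- stagewise_design(cs, list(
    design_stage(0, c(A = 1, B = 0), c(A = 0.5, B = 0))))
  expect_false(validate_design(zero_stage)$ok)

  # validation never mutates its input
  before <- unclass(bad_simplex)
  invisible(validate_design(bad_simplex))
  expect_identical(unclass(bad_simplex), before)
})

test_that("unroll_schedule implements the square-periodic rule", {
  d <- periodic_design(cue_set("A"), 160, c(A = 1), c(A = 1),
                       c(A = 0.5), c(A = 0), half_period = 0.5)
  sch <- unroll_schedule(d)
  expect_equal(unname(sch$outcome_probs[1:80, "A"]), rep(0.5, 80))
  expect_equal(unname(sch$outcome_probs[81:160, "A"]), rep(0, 80))

  # T = 1: a single half-period spans the experiment
  d1 <- periodic_design(cue_set("A"), 40, c(A = 1), c(A = 1),
                        c(A = 0.3), c(A = 0.9), half_period = 1)
  expect_equal(unname(unroll_schedule(d1)$outcome_probs[, "A"]), rep(0.3, 40))

  # T = 0.25, 100 trials: levels switch at 0-based trials 25, 50, 75
  d2 <- periodic_design(cue_set("A"), 100, c(A = 1), c(A = 1),
                        c(A = 0.8), c(A = 0.2), half_period = 0.25)
  p <- unname(unroll_schedule(d2)$outcome_probs[, "A"])
  expect_equal(p, rep(c(0.8, 0.2, 0.8, 0.2), each = 25))

  expect_error(unroll_schedule(
    stagewise_design(cue_set("A"), list(design_stage(0, c(A = 1), c(A = 1))))),
    "invalid design")
})

test_that("a two-stage stage-wise design equals the periodic design with T = 0.5", {
  cs <- cue_set(c("A", "B"))
  sw <- stagewise_design(cs, list(
    design_stage(30, c(A = 0.6, B = 0.4), c(A = 0.7, B = 0.1)),
    design_stage(30, c(A = 0.2, B = 0.8), c(A = 0.0, B = 0.9))))
  pe <- periodic_design(cs, 60,
                        cue_p1 = c(A = 0.6, B = 0.4), cue_p2 = c(A = 0.2, B = 0.8),
                        outcome_p1 = c(A = 0.7, B = 0.1),
                        outcome_p2 = c(A = 0.0, B = 0.9),
                        half_period = 0.5)
  s1 <- unroll_schedule(sw)
  s2 <- unroll_schedule(pe)
  expect_equal(s1$cue_probs, s2$cue_probs)
  expect_equal(s1$outcome_probs, s2$outcome_probs)
})

test_that("sample_realization is seeded, Bernoulli-consistent and cue-faithful", {
  d <- single_cue_design(10, 1)
  r <- sample_realization(unroll_schedule(d), seed = 11)
  expect_equal(r$outcome, rep(1L, 10))

  r2 <- sample_realization(unroll_schedule(d), seed = 11)
  expect_identical(r, r2)

  big <- single_cue_design(10000, 0.5)
  rb <- sample_realization(unroll_schedule(big), seed = 5)
  expect_lt(abs(mean(rb$outcome) - 0.5), 0.015)   # binomial 3-sigma band

  # empirical cue frequencies match cue_probs: chi-square GOF at alpha = 0.01
  cs <- cue_set(c("A", "B", "C"))
  dd <- stagewise_design(cs, list(
    design_stage(10000, c(A = 0.5, B = 0.3, C = 0.2),
                 c(A = 0.5, B = 0.5, C = 0.5))))
  sch <- unroll_schedule(dd)
  rejections <- 0L
  for (s in 1:20) {
    rr <- sample_realization(sch, seed = 100 + s)
    counts <- table(factor(rr$stimulus, levels = c("A", "B", "C")))
    pv <- suppressWarnings(
      stats::chisq.test(counts, p = c(0.5, 0.3, 0.2))$p.value)
    if (pv < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2L)
})

test_that("design spaces have the documented dimensionality and round-trip", {
  sp2 <- design_space("stage-wise", bb_cues(), stage_trials = c(25, 25))
  expect_equal(sp2$dim, 10L)
  sp3 <- design_space("stage-wise", cue_set(c("A", "B")),
                      stage_trials = c(60, 60))
  expect_equal(sp3$dim, 6L)
  sp1 <- design_space("periodic", cue_set("A"), n_trials = 160)
  expect_equal(sp1$dim, 3L)

  # to_vector o from_vector is the identity on random vectors
  for (sp in list(sp1, sp2, sp3)) {
    set.seed(42)
    for (i in 1:25) {
      v <- runif(sp$dim)
      d <- from_vector(sp, v)
      expect_equal(unname(to_vector(sp, d)), v, tolerance = 1e-10)
    }
  }
  expect_error(from_vector(sp1, c(0.5, 1.2, 0.5)), "outside")
  expect_error(from_vector(sp1, c(0.5, 0.5)), "length")
})

test_that("from_vector always yields a valid design (fuzz)", {
  sp <- design_space("stage-wise", bb_cues(), stage_trials = c(25, 25))
  set.seed(7)
  for (i in 1:1000) {
    d <- from_vector(sp, runif(sp$dim))
    expect_true(validate_design(d)$ok)
  }
})

test_that("designs and realizations survive serialization", {
  dir <- withr::local_tempdir()
  bb <- build_reference_design("backward_blocking")
  p <- file.path(dir, "bb.yaml")
  write_design_yaml(bb, p)
  bb2 <- read_design_yaml(p)
  expect_equal(unroll_schedule(bb2), unroll_schedule(bb))

  pe <- build_reference_design("acquisition_extinction", n_trials = 40)
  p2 <- file.path(dir, "ae.yaml")
  write_design_yaml(pe, p2)
  expect_equal(unroll_schedule(read_design_yaml(p2)), unroll_schedule(pe))

  r <- sample_realization(unroll_schedule(bb), seed = 2)
  pcsv <- file.path(dir, "real.csv")
  write_realization_csv(r, pcsv)
  r2 <- read_realization_csv(pcsv)
  expect_equal(r2$stimulus, r$stimulus)
  expect_equal(r2$outcome, r$outcome)
  expect_equal(r2$trial, seq_len(nrow(r)))   # 1-based trial column
})
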