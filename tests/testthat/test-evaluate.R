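test_that("cles enumerates pairwise superiority with ties at one half", {
  expect_equal(cles(c(1, 2), c(1, 3)), 0.375)
  expect_equal(cles(rep(2, 5), rep(2, 7)), 0.5)
  expect_equal(cles(c(5, 6), c(1, 2)), 1.0)
  expect_error(cles(numeric(0), 1), "empty")
})

test_that("cles matches a brute-force double loop and is complementary", {
  set.seed(11)
  for (i in 1:50) {
    x <- round(rnorm(sample(3:20, 1)), 1)   # rounding forces some ties
    y <- round(rnorm(sample(3:20, 1)), 1)
    brute <- 0
    for (a in x) for (b in y) brute <- brute + (a > b) + 0.5 * (a == b)
    brute <- brute / (length(x) * length(y))
    expect_equal(cles(x, y), brute, tolerance = 1e-12)
    expect_equal(cles(x, y) + cles(y, x), 1, tolerance = 1e-12)
  }
})

test_that("percentile bootstrap CI is seeded and self-consistent", {
  expect_equal(unname(percentile_bootstrap_ci(rep(1, 5), rep(1, 5),
                                              n_boot = 200, seed = 1)),
               c(0.5, 0.5))
  ci1 <- percentile_bootstrap_ci(1:10, 2:11, n_boot = 300, seed = 7)
  ci2 <- percentile_bootstrap_ci(1:10, 2:11, n_boot = 300, seed = 7)
  expect_identical(ci1, ci2)
  expect_error(percentile_bootstrap_ci(1:5, 1:5, n_boot = 50), "n_boot")

  # the interval almost always contains the point estimate
  set.seed(99)
  hits <- 0L
  for (i in 1:100) {
    x <- rnorm(30); y <- rnorm(30, 0.3)
    point <- cles(x, y)
    ci <- percentile_bootstrap_ci(x, y, n_boot = 300, seed = i)
    if (point >= ci["lo"] && point <= ci["hi"]) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("clopper_pearson gives exact beta-quantile intervals", {
  ci <- clopper_pearson(512, 512)
  expect_equal(unname(ci["lo"]), 0.99282, tolerance = 1e-4)
  expect_equal(unname(ci["hi"]), 1)
  expect_equal(unname(clopper_pearson(0, 10)["lo"]), 0)
  ci5 <- clopper_pearson(5, 10)
  expect_equal(unname(ci5), c(0.187, 0.813), tolerance = 1e-3)
  expect_error(clopper_pearson(1, 0), "n must be")
  expect_error(clopper_pearson(11, 10), "successes")

  # contains the observed proportion; width shrinks with n
  for (n in c(20, 80, 320)) {
    s <- round(0.7 * n)
    ci <- clopper_pearson(s, n)
    expect_true(ci["lo"] <= s / n && s / n <= ci["hi"])
  }
  w <- vapply(c(20, 80, 320), function(n) {
    ci <- clopper_pearson(round(0.7 * n), n)
    unname(diff(ci))
  }, 0)
  expect_true(all(diff(w) < 0))
})

test_that("Woolf odds ratios match hand-computed tables and handle zeros", {
  expect_equal(unname(odds_ratio_woolf(50, 100, 50, 100)["or"]), 1)

  # accuracies 971/1024 vs 611/1024: OR = (971*413)/(53*611)
  or <- odds_ratio_woolf(971, 1024, 611, 1024)
  expect_equal(unname(or["or"]), (971 * 413) / (53 * 611), tolerance = 1e-12)
  expect_equal(unname(or["or"]), 12.4, tolerance = 0.01)

  # hand-checked table with all cells >= 5: a=30 b=10 c=15 d=20
  or2 <- odds_ratio_woolf(30, 40, 15, 35)
  se <- sqrt(1 / 30 + 1 / 10 + 1 / 15 + 1 / 20)
  expect_equal(unname(or2["or"]), 4, tolerance = 1e-9)
  expect_equal(unname(or2["lo"]), exp(log(4) - qnorm(0.975) * se),
               tolerance = 1e-9)
  expect_equal(unname(or2["hi"]), exp(log(4) + qnorm(0.975) * se),
               tolerance = 1e-9)

  # zero failures: Haldane-Anscombe correction keeps the OR finite
  or3 <- odds_ratio_woolf(20, 20, 15, 20)
  expect_true(is.finite(or3["or"]) && or3["or"] > 1)
  expect_error(odds_ratio_woolf(0, 0, 1, 2), "at least one")
})

test_that("confusion matrices count truth by selection and yield recovery rates", {
  cm <- confusion_matrix(c("rw", "rw", "krw"), c("rw", "krw", "krw"),
                         c("rw", "krw"))
  expect_equal(unname(cm$matrix), rbind(c(1, 1), c(0, 1)))
  expect_equal(unname(cm$recovery), c(0.5, 1))
  expect_equal(cm$accuracy, 2 / 3)

  perfect <- confusion_matrix(c("a", "b", "a"), c("a", "b", "a"), c("a", "b"))
  expect_equal(unname(perfect$matrix), diag(c(2, 1)))

  # overall accuracy is the row-weighted mean of recovery rates
  set.seed(3)
  for (i in 1:20) {
    truth <- sample(c("m1", "m2", "m3"), 60, replace = TRUE)
    sel <- sample(c("m1", "m2", "m3"), 60, replace = TRUE)
    cm <- confusion_matrix(truth, sel, c("m1", "m2", "m3"))
    rs <- rowSums(cm$matrix)
    expect_equal(cm$accuracy,
                 sum(cm$recovery * rs, na.rm = TRUE) / sum(rs))
  }
  expect_error(confusion_matrix("x", "rw", c("rw", "krw")), "unknown model")
  expect_error(confusion_matrix(c("rw", "rw"), "rw", c("rw", "krw")),
               "length mismatch")
})

test_that("compare_designs assembles CLES, odds ratios and confusion matrices", {
  mk_eval <- function(acc, n, truth, sel) {
    structure(list(mean = mean(acc), se = sd(acc) / sqrt(n), n_sims = n,
                   analysis = "select", utilities = acc,
                   truth_models = truth, selected = sel, n_failed = 0L),
              class = "expected_utility")
  }
  set.seed(4)
  truth <- rep(c("rw", "krw"), each = 20)
  other <- ifelse(truth == "rw", "krw", "rw")
  sel_good <- ifelse(runif(40) < 0.9, truth, other)
  sel_bad <- ifelse(runif(40) < 0.55, truth, "rw")
  e1 <- mk_eval(as.numeric(sel_good == truth), 40, truth, sel_good)
  e2 <- mk_eval(as.numeric(sel_bad == truth), 40, truth, sel_bad)
  rep <- compare_designs(list(optimized = e1, reference = e2),
                         model_space = c("rw", "krw"), n_boot = 200, seed = 1)
  expect_s3_class(rep, "comparison_report")
  expect_true(rep$pairs[["optimized vs reference"]]$cles >= 0.5)
  expect_true(rep$pairs[["optimized vs reference"]]$odds_ratio["or"] >= 1)
  expect_equal(sum(rep$designs$optimized$confusion$matrix), 40)
  cles_xy <- rep$pairs[["optimized vs reference"]]$cles
  cles_yx <- rep$pairs[["reference vs optimized"]]$cles
  expect_equal(cles_xy + cles_yx, 1)
})
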