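test_that("stimulus encoding maps compounds to multi-hot rows and round-trips", {
  cs <- bb_cues()
  real <- data.frame(trial = 1:3, stimulus = c("AB", "A", "B"),
                     outcome = c(1L, 0L, 1L))
  enc <- encode_stimuli(real, cs)
  expect_equal(unname(enc$X), rbind(c(1, 1), c(1, 0), c(0, 1)))
  expect_equal(enc$r, c(1, 0, 1))
  expect_equal(decode_stimuli(enc$X, cs), real$stimulus)
  expect_error(encode_stimuli(data.frame(stimulus = "Z", outcome = 0), cs),
               "unknown stimulus")
})

test_that("rw_step follows the delta rule", {
  s1 <- rw_step(w = 0, x = 1, r = 1, alpha = 0.2)
  expect_equal(s1$delta, 1)
  expect_equal(s1$w, 0.2)
  s2 <- rw_step(s1$w, 1, 1, 0.2)
  expect_equal(s2$delta, 0.8)
  expect_equal(s2$w, 0.36)
  # alpha = 0 freezes the weights
  expect_equal(rw_step(c(0.4, -0.2), c(1, 1), 1, 0)$w, c(0.4, -0.2))
  # absent cues never change
  s3 <- rw_step(c(0.5, 0.1), c(1, 0), 0, 0.3)
  expect_equal(s3$w[2], 0.1)
})

test_that("krw_step matches the scalar Kalman closed form and guards PSD", {
  s <- krw_step(w = 0, Sigma = 1, x = 1, r = 1,
                q_diffusion = 0, r_noise_var = 1)
  expect_equal(s$gain, 0.5)
  expect_equal(s$w, 0.5)
  expect_equal(drop(s$Sigma), 0.5)

  # zero prior uncertainty and no diffusion: no update whatever the outcome
  s0 <- krw_step(0.3, 0, 1, 1, 0, 1)
  expect_equal(s0$w, 0.3)
  expect_equal(drop(s0$Sigma), 0)

  expect_error(krw_step(c(0, 0), matrix(c(1, 2, 2, 1), 2), c(1, 0), 1, 0, 1),
               "positive semidefinite")
})

test_that("rwph_step updates weights and associabilities for presented cues only", {
  s <- rwph_step(V = 0, assoc = 0.5, x = 1, r = 1, kappa = 0.4, eta = 0.2)
  expect_equal(s$delta, 1)
  expect_equal(s$V, 0.2)
  expect_equal(s$assoc, 0.6)

  # eta = 1: associability jumps to |delta|
  V <- c(0.4, 0); a <- c(0.3, 0.9); x <- c(1, 0)
  s1 <- rwph_step(V, a, x, r = 1, kappa = 0.5, eta = 1)
  expect_equal(s1$assoc, c(0.6, 0.9))

  # eta = 0 reduces to the delta rule with rate kappa * alpha0
  a0 <- 0.5; kap <- 0.4
  s2 <- rwph_step(c(0.1, 0.2), c(a0, a0), c(1, 1), 1, kap, eta = 0)
  s_rw <- rw_step(c(0.1, 0.2), c(1, 1), 1, kap * a0)
  expect_equal(s2$V, s_rw$w)
  expect_equal(s2$assoc, c(a0, a0))
})

test_that("emit_response implements the three mappings", {
  expect_equal(emit_response(V = 0.4, x = 1, sigma_obs = 0, mapping = "V"), 0.4)
  expect_equal(emit_response(V = 0.4, x = 1, sigma_obs = 0,
                             mapping = "V_plus_alpha", assoc = 0.8, omega = 0),
               0.4)                                   # omega = 0 equals V mapping
  expect_equal(emit_response(V = 0.4, x = 1, sigma_obs = 0,
                             mapping = "V_plus_alpha", assoc = 0.8, omega = 0.5),
               0.6)                                   # convex combination
  expect_equal(emit_response(V = 0.4, x = 1, sigma_obs = 0,
                             mapping = "alpha", assoc = 0.8), 0.8)
})

test_that("vectorised filters agree exactly with per-trial step iteration", {
  tr <- random_trials(300, seed = 21)
  X <- tr$X; r <- tr$r

  # RW
  f <- condesign:::rw_filter_cpp(X, r, 0.27, 0, 1)
  w <- c(0, 0); m <- numeric(300)
  for (t in 1:300) {
    m[t] <- sum(X[t, ] * w)
    expect_equal(unname(f$V[t, ]), w)
    w <- rw_step(w, X[t, ], r[t], 0.27)$w
  }
  expect_equal(f$m, m)

  # KRW (diffusion folded into the step, prediction-time covariance recorded)
  f <- condesign:::krw_filter_cpp(X, r, 0, 0.8, 0.02, 0.4)
  w <- c(0, 0); S <- diag(0.8, 2)
  for (t in 1:300) {
    st <- krw_step(w, S, X[t, ], r[t], 0.02, 0.4)
    expect_equal(unname(f$V[t, ]), w, tolerance = 1e-12)
    expect_equal(unname(f$Sigma[t, , ]), unname(S + diag(0.02, 2)),
                 tolerance = 1e-12)
    expect_equal(unname(f$gain[t, ]), st$gain, tolerance = 1e-12)
    w <- st$w; S <- st$Sigma
  }

  # RWPH
  f <- condesign:::rwph_filter_cpp(X, r, 0.5, 0.3, 0.7, 0)
  V <- c(0, 0); a <- c(0.7, 0.7)
  for (t in 1:300) {
    expect_equal(unname(f$V[t, ]), V, tolerance = 1e-12)
    expect_equal(unname(f$assoc[t, ]), a, tolerance = 1e-12)
    st <- rwph_step(V, a, X[t, ], r[t], 0.5, 0.3)
    V <- st$V; a <- st$assoc
  }
})

test_that("noiseless RW simulation follows the closed-form learning curve", {
  d <- single_cue_design(12, 1)
  ds <- simulate_dataset(d, "rw", list(alpha = 0.2, sigma_obs = 0), seed = 1)
  expect_equal(ds$response, 1 - 0.8^(0:11))
  expect_error(simulate_dataset(d, "not_a_model", list(), seed = 1),
               "unknown model_id")
  ds2 <- simulate_dataset(d, "rw", list(alpha = 0.2, sigma_obs = 0), seed = 1)
  expect_identical(ds, ds2)
})

test_that("RW weights asymptote at the reinforcement probability", {
  for (p in c(0.25, 0.5, 0.75)) {
    d <- single_cue_design(2000, p)
    ds <- simulate_dataset(d, "rw", list(alpha = 0.1, sigma_obs = 0),
                           seed = round(1000 * p), latents = TRUE)
    w <- attr(ds, "latents")$V[, 1]
    expect_lt(abs(mean(w[1601:2000]) - p), 0.05)
  }
})

test_that("backward blocking diminishes cue B under KRW but not under RW", {
  cs <- bb_cues()
  d <- stagewise_design(cs, list(
    design_stage(20, c(AB = 1), c(AB = 1)),
    design_stage(20, c(A = 1), c(A = 1))))
  krw_par <- list(w0_var = 1, q_diffusion = 0.01, r_noise_var = 0.2,
                  sigma_obs = 0)
  ds_k <- simulate_dataset(d, "krw", krw_par, seed = 1, latents = TRUE)
  ds_r <- simulate_dataset(d, "rw", list(alpha = 0.2, sigma_obs = 0),
                           seed = 1, latents = TRUE)
  wB_k <- attr(ds_k, "latents")$V[, 2]
  wB_r <- attr(ds_r, "latents")$V[, 2]
  # KRW: responding to B is revalued downward during the A+ stage
  expect_lt(wB_k[40], wB_k[21])
  # RW: B's weight cannot change while B is absent
  expect_equal(wB_r[40], wB_r[21])
  # the AB+ stage induces a negative weight correlation (sign check)
  Sig <- attr(ds_k, "latents")$Sigma
  expect_lt(Sig[20, 1, 2], 0)
})

test_that("KRW prediction-time covariances stay symmetric PSD over random fuzz", {
  tr <- random_trials(10000, seed = 33)
  f <- condesign:::krw_filter_cpp(tr$X, tr$r, 0, 2, 0.05, 0.1)
  min_eig <- Inf
  for (t in seq(1, 10000, by = 7)) {
    S <- f$Sigma[t, , ]
    expect_equal(S[1, 2], S[2, 1])
    e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    min_eig <- min(min_eig, e)
  }
  expect_gte(min_eig, -1e-10)
})

test_that("RWPH(V) with eta = 0 reproduces the RW likelihood exactly", {
  d <- switching_design(120)
  ds <- simulate_dataset(d, "rw", list(alpha = 0.35, sigma_obs = 0.1), seed = 9)
  for (alpha in c(0.12, 0.35, 0.8)) {
    ll_rw <- log_likelihood("rw", list(alpha = alpha, sigma_obs = 0.1), ds)
    ll_ph <- log_likelihood("rwph_v",
                            list(kappa = alpha / 0.5, eta = 0, alpha0 = 0.5,
                                 sigma_obs = 0.1), ds)
    expect_equal(ll_ph, ll_rw, tolerance = 1e-9)
  }
})

test_that("log_likelihood matches a naive per-trial oracle", {
  d <- single_cue_design(5, 0.6)
  ds <- simulate_dataset(d, "rw", list(alpha = 0.3, sigma_obs = 0.2), seed = 4)
  par <- list(alpha = 0.25, sigma_obs = 0.3)
  ll <- log_likelihood("rw", par, ds)

  # oracle: iterate rw_step by hand and sum Gaussian log-densities
  w <- 0; ll_oracle <- 0
  for (t in 1:5) {
    m <- w * 1
    ll_oracle <- ll_oracle + dnorm(ds$response[t], m, 0.3, log = TRUE)
    w <- rw_step(w, 1, ds$outcome[t], 0.25)$w
  }
  expect_equal(ll, ll_oracle, tolerance = 1e-10)

  # zero residuals at sigma = 1: -(n/2) log(2 pi)
  ds0 <- simulate_dataset(d, "rw", list(alpha = 0.3, sigma_obs = 0), seed = 4)
  ll0 <- log_likelihood("rw", list(alpha = 0.3, sigma_obs = 1), ds0)
  expect_equal(ll0, -(5 / 2) * log(2 * pi), tolerance = 1e-10)

  # adding 1.0 to one residual at sigma = 1 costs exactly 0.5
  ds1 <- ds0
  ds1$response[3] <- ds1$response[3] + 1
  expect_equal(ll0 - log_likelihood("rw", list(alpha = 0.3, sigma_obs = 1), ds1),
               0.5, tolerance = 1e-10)

  expect_error(log_likelihood("rw", list(alpha = 0.3, sigma_obs = 0), ds),
               "sigma_obs")
})
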