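# Gaussian-process regression surrogate used by the Bayesian optimizer:
# anisotropic Matern-5/2 kernel with a fitted observation-noise term,
# hyperparameters set by maximizing the log marginal likelihood with
# multi-start L-BFGS-B on log scale. Inputs are assumed to live in [0,1]^d;
# outputs are standardized internally.

matern52_kernel <- function(X1, X2, ell, sf2) {
  d <- ncol(X1)
  r2 <- matrix(0, nrow(X1), nrow(X2))
  for (j in seq_len(d)) {
    dj <- outer(X1[, j], X2[, j], "-") / ell[j]
    r2 <- r2 + dj * dj
  }
  r <- sqrt(pmax(r2, 0))
  s5r <- sqrt(5) * r
  sf2 * (1 + s5r + (5 / 3) * r2) * exp(-s5r)
}

gp_nlml <- function(theta, X, yc) {
  d <- ncol(X)
  ell <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1L])
  sn2 <- exp(theta[d + 2L])
  n <- nrow(X)
  K <- matern52_kernel(X, X, ell, sf2) + diag(sn2 + 1e-8, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  a <- backsolve(L, forwardsolve(t(L), yc))
  as.numeric(0.5 * crossprod(yc, a) + sum(log(diag(L))) + 0.5 * n * log(2 * pi))
}

# Fit the GP. `noise_floor` keeps the fitted noise away from exact zero so
# Monte-Carlo noisy objectives are never interpolated exactly.
gp_fit <- function(X, y, seed = 1L, n_restarts = 2L, noise_floor = 1e-6) {
  X <- as.matrix(X)
  d <- ncol(X)
  mu <- mean(y)
  s <- sd(y)
  if (!is.finite(s) || s < 1e-12) s <- 1
  yc <- (y - mu) / s
  lo <- c(rep(log(0.02), d), log(1e-4), log(max(noise_floor, 1e-8)))
  hi <- c(rep(log(10), d), log(100), log(2))
  base <- c(rep(log(0.3), d), log(1), log(0.05))
  starts <- rbind(base,
                  with_seed(derive_seed(seed, 7L),
                            matrix(runif(n_restarts * (d + 2L), lo, hi),
                                   nrow = n_restarts, byrow = TRUE)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(pmin(pmax(starts[i, ], lo), hi), gp_nlml, X = X, yc = yc,
            method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 200L)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) best <- list(par = base, value = gp_nlml(base, X, yc))
  theta <- best$par
  ell <- exp(theta[seq_len(d)])
  sf2 <- exp(theta[d + 1L])
  sn2 <- exp(theta[d + 2L])
  K <- matern52_kernel(X, X, ell, sf2) + diag(sn2 + 1e-8, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(X = X, y = y, mu = mu, s = s, ell = ell, sf2 = sf2,
                 sn2 = sn2, L = L, alpha = alpha, nlml = best$value),
            class = "gp_model")
}

# Posterior mean and latent (noise-free) s.d. at new points, on the original
# output scale.
gp_predict <- function(gp, Xnew) {
  Xnew <- as.matrix(Xnew)
  Ks <- matern52_kernel(gp$X, Xnew, gp$ell, gp$sf2)
  mean_c <- drop(crossprod(Ks, gp$alpha))
  v <- forwardsolve(t(gp$L), Ks)
  var_c <- pmax(gp$sf2 - colSums(v * v), 0)
  list(mean = gp$mu + gp$s * mean_c, sd = gp$s * sqrt(var_c))
}

# Expected improvement (maximization) with exploration offset xi.
expected_improvement <- function(mu, sdev, best, xi = 0.01) {
  z <- ifelse(sdev > 0, (mu - best - xi) / sdev, 0)
  ei <- (mu - best - xi) * pnorm(z) + sdev * dnorm(z)
  ifelse(sdev > 0, pmax(ei, 0), pmax(mu - best - xi, 0))
}
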