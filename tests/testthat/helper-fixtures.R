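# Shared fixtures and independent oracles, all built in code.

# 6-row toy with two disjoint missingness patterns:
# rows 1-3 observe {x1, x2}, rows 4-6 observe {x2, x3}.
two_pattern_toy <- function() {
  X <- matrix(NA_real_, 6, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  X[1:3, c("x1", "x2")] <- c(1, 2, 3, 4, 6, 5)    # not collinear
  X[4:6, c("x2", "x3")] <- c(7, 9, 8, 10, 11, 14)
  tabular_dataset(1:6, X)
}

random_missing_toy <- function(n = 12, p = 4, miss = 0.3) {
  X <- matrix(rnorm(n * p), n, p)
  X[matrix(runif(n * p) < miss, n, p)] <- NA
  # keep at least one observed value per column
  for (j in seq_len(p)) if (all(is.na(X[, j]))) X[1, j] <- rnorm(1)
  tabular_dataset(rnorm(n), X)
}

# Exact posterior of the semi-conjugate Bayesian linear model by 1-D
# quadrature over the noise precision tau. beta | tau, y is normal in
# closed form; the tau marginal p(tau | y) is evaluated on a fine grid via
# the Gaussian marginal likelihood y | tau ~ N(X m0, X V0 X' + I/tau),
# computed through one eigendecomposition of X V0 X'. Independent of the
# package's sampler.
quadrature_posterior <- function(X, y, m0, v0, a0, b0, n_grid = 4000) {
  n <- nrow(X); q <- ncol(X)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  S <- X %*% (v0 * t(X))               # X V0 X'
  es <- eigen((S + t(S)) / 2, symmetric = TRUE)
  r <- drop(y - X %*% m0)
  u2 <- drop(crossprod(es$vectors, r))^2
  lam <- pmax(es$values, 0)

  log_post_tau <- function(tau) {
    # log p(tau) + log N(y; X m0, S + I/tau), up to a constant
    dvals <- lam + 1 / tau
    (a0 - 1) * log(tau) - b0 * tau -
      0.5 * sum(log(dvals)) - 0.5 * sum(u2 / dvals)
  }
  # grid spanning far beyond the plausible posterior range of tau
  rss <- sum(stats::lm.fit(X, y)$residuals^2)
  guess <- (a0 + n / 2) / (b0 + rss / 2)
  taus <- exp(seq(log(guess) - 8, log(guess) + 8, length.out = n_grid))
  lp <- vapply(taus, log_post_tau, numeric(1))
  w <- exp(lp - max(lp)) * taus        # log-spaced grid: dtau = tau dlog
  w <- w / sum(w)

  mean_given_tau <- vapply(taus, function(tau) {
    A <- tau * XtX + diag(1 / v0, q)
    drop(solve(A, tau * Xty + m0 / v0))
  }, numeric(q))
  mean_given_tau <- matrix(mean_given_tau, nrow = q)
  list(beta_mean = drop(mean_given_tau %*% w),
       tau_mean = sum(taus * w))
}

# Monte-Carlo standard error of a chain mean by batch means.
mcse <- function(x, n_batch = 25) {
  b <- floor(length(x) / n_batch)
  bm <- vapply(seq_len(n_batch), function(i) mean(x[((i - 1) * b + 1):(i * b)]),
               numeric(1))
  stats::sd(bm) / sqrt(n_batch)
}

# Tiny scenario for fast end-to-end runs.
small_scenario <- function(p = 5, seed = 1, n_train = 60,
                           n_complete_extra = 10, n_test = 40,
                           missing_rate = 0.4) {
  build_scenario(scenario_config(p = p, n_train = n_train,
                                 n_complete_extra = n_complete_extra,
                                 n_test = n_test,
                                 missing_rate = missing_rate),
                 seed = seed)
}

fast_mcmc <- function(seed = NULL) mcmc_config(1200, 200, seed = seed)
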