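make_sub <- function(X, y) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(row_ids = seq_along(y), predictor_subset = colnames(X),
                 outcome = y, predictors = X),
            class = "sub_dataset")
}

test_that("Gibbs posterior matches the exact quadrature posterior", {
  set.seed(1)
  X <- cbind(1, matrix(rnorm(400), 200, 2))
  beta_true <- c(0.5, -1, 0.25)
  y <- drop(X %*% beta_true) + rnorm(200, 0, 0.6)
  sub <- make_sub(X[, -1], y)
  prior <- belief_state(sub$predictor_subset)

  draws <- gibbs_fit(sub, prior, mcmc_config(22000, 2000, seed = 99))
  oracle <- quadrature_posterior(X, y, m0 = rep(0, 3), v0 = rep(100, 3),
                                 a0 = 2.5, b0 = 25)
  for (j in 1:3) {
    se <- mcse(draws$beta[, j])
    expect_lt(abs(mean(draws$beta[, j]) - oracle$beta_mean[j]), 3 * se)
  }
  expect_lt(abs(mean(draws$tau) - oracle$tau_mean), 4 * mcse(draws$tau))
})

test_that("a near-degenerate prior pins its coefficient at the prior mean", {
  set.seed(2)
  X <- matrix(rnorm(300), 300, 1)
  y <- drop(0.8 * X) + rnorm(300, 0, 0.3)
  sub <- make_sub(X, y)
  prior <- belief_state("x1")
  prior$variance["x1"] <- 1e-12
  draws <- gibbs_fit(sub, prior, fast_mcmc(seed = 3))
  expect_lt(abs(mean(draws$beta[, "x1"])), 1e-4)
})

test_that("with weak priors and tiny noise the posterior mean approaches OLS", {
  set.seed(4)
  X <- matrix(rnorm(500), 250, 2)
  y <- drop(X %*% c(1, -2)) + rnorm(250, 0, 1e-4)
  sub <- make_sub(X, y)
  prior <- belief_state(sub$predictor_subset, coef_var = 1e6)
  draws <- gibbs_fit(sub, prior, mcmc_config(4000, 1000, seed = 5))
  ols <- coef(lm(y ~ X))
  post <- colMeans(draws$beta)
  expect_lt(abs(post[["x1"]] - ols[[2]]), 2e-3)
  expect_lt(abs(post[["x2"]] - ols[[3]]), 2e-3)
})

test_that("singular fragment designs are rejected with advice", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))  # collinear
  sub <- structure(list(row_ids = 1:4, predictor_subset = c("a", "b"),
                        outcome = rnorm(4), predictors = X),
                   class = "sub_dataset")
  expect_error(gibbs_fit(sub, belief_state(c("a", "b")), fast_mcmc(1)),
               "min_ratio")
})

test_that("posterior summaries moment-match coefficients and precision", {
  # constant coefficient draws hit the variance floor with a warning
  fake <- structure(list(beta = matrix(1.5, 500, 1,
                                       dimnames = list(NULL, "x1")),
                         tau = rgamma(500, 3, 2)),
                    class = "dmu_draws")
  expect_warning(s <- summarize_posterior(fake), "floored")
  expect_equal(unname(s$mean), 1.5)
  expect_equal(unname(s$variance), 1e-10)

  # gamma moment matching recovers shape/rate from large samples
  set.seed(6)
  fake2 <- structure(list(beta = matrix(rnorm(1e5), ncol = 1,
                                        dimnames = list(NULL, "x1")),
                          tau = rgamma(1e5, shape = 2.5, rate = 25)),
                     class = "dmu_draws")
  s2 <- summarize_posterior(fake2)
  expect_lt(abs(s2$precision[["shape"]] - 2.5) / 2.5, 0.1)
  expect_lt(abs(s2$precision[["rate"]] - 25) / 25, 0.1)

  expect_error(summarize_posterior(
    structure(list(beta = matrix(0, 10, 1), tau = rep(1, 10)),
              class = "dmu_draws")), "100 retained")
})

test_that("default beliefs are N(0,100) with Gamma(5/2, 50/2) precision", {
  b <- belief_state(c("x1", "x2"))
  expect_equal(unname(b$mean), c(0, 0, 0))
  expect_equal(unname(b$variance), c(100, 100, 100))
  expect_equal(unname(b$precision), c(5 / 2, 50 / 2))
})

test_that("the chain updates only the columns a fragment carries", {
  toy <- two_pattern_toy()
  # x3 never jointly observed with x1: give rows 4-6 only x2
  X <- toy$predictors
  X[4:6, "x3"] <- NA
  d <- tabular_dataset(toy$outcome, X)
  cl <- cluster_rows(binarize_missingness(d), 2)
  fr <- fragment(d, cl, min_ratio = 1)
  m <- dmu_fit(fr, mcmc = fast_mcmc(seed = 7))
  # x3 appears in no usable fragment: prior belief untouched
  expect_equal(unname(m$mean["x3"]), 0)
  expect_equal(unname(m$variance["x3"]), 100)
  expect_equal(length(m$history), length(fr$subdatasets))
})

test_that("a single-fragment chain equals one Gibbs fit plus summary", {
  set.seed(8)
  d <- tabular_dataset(rnorm(40), matrix(rnorm(80), 40, 2))
  fr <- fragment(d, cluster_rows(binarize_missingness(d), 1))
  m <- dmu_fit(fr, mcmc = fast_mcmc(seed = 44), center = FALSE)

  set.seed(44)
  draws <- gibbs_fit(fr$subdatasets[[1]], belief_state(d$column_names),
                     fast_mcmc())
  s <- summarize_posterior(draws)
  expect_equal(m$mean[names(s$mean)], s$mean)
  expect_equal(m$precision, s$precision)
})

test_that("fragments with disjoint predictors update beliefs independently", {
  set.seed(9)
  X <- matrix(NA_real_, 120, 2, dimnames = list(NULL, c("x1", "x2")))
  X[1:60, "x1"] <- rnorm(60)
  X[61:120, "x2"] <- rnorm(60)
  y <- ifelse(is.na(X[, "x2"]), 0.7 * X[, "x1"], -0.4 * X[, "x2"]) +
    rnorm(120, 0, 0.4)
  d <- tabular_dataset(y, X)
  fr <- fragment(d, cluster_rows(binarize_missingness(d), 2), min_ratio = 1)
  m <- dmu_fit(fr, mcmc = fast_mcmc(seed = 10), center = FALSE,
               chain_precision = FALSE)

  for (sub in fr$subdatasets) {
    set.seed(10)
    ind <- summarize_posterior(gibbs_fit(sub, belief_state(d$column_names),
                                         fast_mcmc()))
    j <- sub$predictor_subset
    # slope beliefs for a column come only from the fragment carrying it
    expect_equal(m$mean[j], ind$mean[j], tolerance = 0.05)
  }
})

test_that("identical seeds reproduce the belief state exactly", {
  sc <- small_scenario(seed = 12)
  fr <- fragment(sc$train,
                 cluster_rows(binarize_missingness(sc$train), 4),
                 min_ratio = 1)
  m1 <- dmu_fit(fr, mcmc = fast_mcmc(seed = 77))
  m2 <- dmu_fit(fr, mcmc = fast_mcmc(seed = 77))
  expect_identical(m1$mean, m2$mean)
  expect_identical(m1$variance, m2$variance)
})

test_that("plug-in prediction uses posterior means and centring", {
  sc <- small_scenario(seed = 13)
  m <- structure(list(mean = c("(Intercept)" = 2,
                               stats::setNames(rep(0, 5), paste0("x", 1:5))),
                      variance = stats::setNames(rep(1, 6),
                                                 c("(Intercept)", paste0("x", 1:5))),
                      precision = c(shape = 2.5, rate = 25),
                      schema = paste0("x", 1:5),
                      center = stats::setNames(rep(0, 5), paste0("x", 1:5)),
                      history = list()),
                 class = "dmu_model")
  expect_equal(predict(m, sc$test), rep(2, n_rows(sc$test)))

  # true-coefficient model on noiseless data predicts perfectly
  cfg <- scenario_config(p = 5, corr_range = c(0, 0))
  cfg$noise_var <- 1e-20
  d <- generate_complete_data(cfg, diag(5), 100)
  m$mean[] <- c(0, 0.2, 0.3, 0.4, 0, 0)
  expect_lt(mean((d$outcome - predict(m, d))^2), 1e-10)
})

test_that("a noiseless single-fragment fit predicts near-perfectly", {
  set.seed(14)
  cfg <- scenario_config(p = 5, corr_range = c(0, 0))
  cfg$noise_var <- 1e-12
  d <- generate_complete_data(cfg, diag(5), 800)
  fr <- fragment(d, cluster_rows(binarize_missingness(d), 1))
  m <- dmu_fit(fr, mcmc = mcmc_config(3000, 500, seed = 15))
  test_d <- generate_complete_data(cfg, diag(5), 200)
  expect_lt(mean((test_d$outcome - predict(m, test_d))^2), 1e-4)
})

test_that("an empty fragmentation warns and keeps the prior", {
  d <- tabular_dataset(1:3, matrix(rnorm(6), 3, 2))
  fr <- fragment(d, cluster_rows(binarize_missingness(d), 1), min_ratio = 10)
  expect_warning(m <- dmu_fit(fr), "empty fragmentation")
  expect_equal(unname(m$mean), rep(0, 3))
})

test_that("model JSON round trip preserves beliefs to full precision", {
  sc <- small_scenario(seed = 16)
  fr <- fragment(sc$train,
                 cluster_rows(binarize_missingness(sc$train), 3),
                 min_ratio = 1)
  m <- dmu_fit(fr, mcmc = fast_mcmc(seed = 17))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(m2$mean, m$mean, tolerance = 1e-14)
  expect_equal(m2$variance, m$variance, tolerance = 1e-14)
  expect_equal(m2$center, m$center, tolerance = 1e-14)
  expect_equal(m2$precision, m$precision, tolerance = 1e-14)
  expect_equal(predict(m2, sc$test), predict(m, sc$test),
               tolerance = 1e-12)
})
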