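test_that("mean imputation fills with observed means and shrinks variance", {
  d <- tabular_dataset(1:3, matrix(c(1, NA, 3, 4, 5, 6), 3, 2))
  imp <- mean_impute(d)
  expect_equal(unname(imp$predictors[, 1]), c(1, 2, 3))
  expect_equal(unname(imp$predictors[, 2]), c(4, 5, 6))

  complete <- tabular_dataset(1:3, matrix(rnorm(6), 3, 2))
  expect_identical(mean_impute(complete)$predictors, complete$predictors)

  set.seed(1)
  big <- random_missing_toy(n = 200, p = 3, miss = 0.4)
  imp2 <- mean_impute(big)
  for (j in 1:3) {
    obs <- big$mask[, j] == 1L
    expect_lte(var(imp2$predictors[, j]), var(big$predictors[obs, j]))
    expect_identical(imp2$predictors[obs, j], big$predictors[obs, j])
  }

  allmiss <- tabular_dataset(1:3, matrix(c(NA, NA, NA, 1, 2, 3), 3, 2,
                                         dimnames = list(NULL, c("a", "b"))))
  expect_error(mean_impute(allmiss), "'a'")
})

test_that("complete-case regression ignores incomplete rows entirely", {
  set.seed(2)
  X <- matrix(rnorm(120), 40, 3)
  y <- drop(X %*% c(1, -1, 0.5)) + rnorm(40, 0, 0.2)
  complete <- tabular_dataset(y, X)
  m <- cca_regress(complete)
  expect_equal(unname(coef(m$fit)), unname(coef(lm(y ~ X))))

  # poke missing values into some rows, perturb those rows arbitrarily
  X2 <- rbind(X, matrix(rnorm(30), 10, 3))
  y2 <- c(y, rnorm(10))
  X2[41:50, 1] <- NA
  d2 <- tabular_dataset(y2, X2)
  m2 <- cca_regress(d2)
  X3 <- X2; X3[41:50, 2:3] <- 1e6
  m3 <- cca_regress(tabular_dataset(y2, X3))
  expect_equal(coef(m2$fit), coef(m3$fit))

  # no complete rows: the documented infeasibility error
  X4 <- X; X4[, 1] <- NA
  expect_error(cca_regress(tabular_dataset(y, X4)),
               class = "dmu_infeasible_error")
})

test_that("PMM imputes only observed donor values", {
  set.seed(3)
  for (rep in 1:8) {
    toy <- random_missing_toy(n = 20, p = 3, miss = 0.25)
    imp <- suppressWarnings(pmm_impute(toy, m = 2, k_donors = 2,
                                       n_cycles = 2))
    for (d in imp$datasets) for (j in 1:3) {
      obs <- toy$mask[, j] == 1L
      expect_true(all(d$predictors[!obs, j] %in% toy$predictors[obs, j]))
      expect_identical(d$predictors[obs, j], toy$predictors[obs, j])
    }
  }
})

test_that("single-donor PMM on a collinear toy picks the nearest prediction's value", {
  # x2 = 2 * x1 exactly; one missing x2 must copy the observed x2 whose
  # prediction is closest, found here by brute force
  x1 <- c(1, 2, 3, 4, 5)
  x2 <- 2 * x1
  x2_obs <- x2; x2_obs[3] <- NA
  d <- tabular_dataset(rnorm(5), cbind(x1 = x1, x2 = x2_obs))
  imp <- pmm_impute(d, m = 1, k_donors = 1, n_cycles = 1, seed = 4)
  # predictions for x2 are exactly 2*x1; nearest observed prediction to
  # row 3 (pred 6) is row 2 (pred 4) or row 4 (pred 8) -> brute force:
  preds <- 2 * x1
  donors <- which(!is.na(x2_obs))
  nearest <- donors[which.min(abs(preds[donors] - preds[3]))]
  expect_equal(unname(imp$datasets[[1]]$predictors[3, "x2"]), x2[nearest])
})

test_that("PMM default donor count follows the usual convention", {
  expect_equal(formals(pmm_impute)$k_donors, 5)
  d <- tabular_dataset(1:4, matrix(c(1, NA, 3, 4, 5, 6, 7, 8), 4, 2))
  expect_error(pmm_impute(d, k_donors = 4), "k_donors")
})

test_that("Rubin pooling reproduces hand-computed decompositions", {
  set.seed(5)
  base <- random_missing_toy(n = 60, p = 2, miss = 0.2)
  imp <- pmm_impute(base, m = 2, seed = 6)

  # identical imputations: between-variance zero, pooled = single fit
  imp_same <- imp
  imp_same$datasets[[2]] <- imp_same$datasets[[1]]
  pm <- pooled_regress(imp_same)
  single <- lm(imp_same$datasets[[1]]$outcome ~
                 imp_same$datasets[[1]]$predictors)
  expect_equal(unname(pm$coefficients), unname(coef(single)))
  expect_equal(unname(pm$between_var), rep(0, 3))
  expect_equal(pm$total_var, pm$within_var)

  # m = 2 with estimates 1 and 3: pooled 2, between 2, total within + 3
  pm2 <- pooled_regress(imp)
  est <- vapply(imp$datasets, function(d)
    coef(lm(d$outcome ~ d$predictors)), numeric(3))
  expect_equal(unname(pm2$coefficients), unname(rowMeans(est)))
  expect_equal(unname(pm2$total_var),
               unname(pm2$within_var + 1.5 * pm2$between_var))

  # pooled predictions are the mean of per-imputation predictions
  newx <- matrix(rnorm(10), 5, 2,
                 dimnames = list(NULL, base$column_names))
  per <- vapply(imp$datasets, function(d) {
    cf <- coef(lm(d$outcome ~ d$predictors))
    cf[1] + drop(newx %*% cf[-1])
  }, numeric(5))
  expect_equal(predict(pm2, newx), unname(rowMeans(per)))
})

test_that("hand-made Rubin example: estimates (1, 3) pool to 2 with between 2", {
  est <- c(1, 3)
  m <- 2
  expect_equal(mean(est), 2)
  expect_equal(var(est), 2)
  expect_equal(0.5 + (1 + 1 / m) * var(est), 0.5 + 3)
})

test_that("PMM-pooled slope is approximately unbiased under light MCAR", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(400)
    y <- 1 + 0.8 * x + rnorm(400, 0, 0.5)
    xm <- x; xm[runif(400) < 0.2] <- NA
    d <- tabular_dataset(y, cbind(x1 = xm))
    pm <- pooled_regress(pmm_impute(d, include_outcome = TRUE,
                                    seed = s + 100))
    abs(pm$coefficients[["x1"]] - 0.8) <= 3 * sqrt(pm$total_var[["x1"]])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
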