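#' Simulation scenario configuration
#'
#' Describes one simulated study condition: a linear model
#' `y = beta0 + 0.2 x1 + 0.3 x2 + 0.4 x3 + e`, `e ~ N(0, noise_var)`, with
#' `x1 ~ Beta(7, 2)`, `x2 ~ U(0, 2)` and `x3..xp ~ N(0, 1)` coupled through
#' a random correlation matrix among the first five predictors. Training
#' rows undergo per-predictor MCAR amputation; a scenario with
#' `n_complete_extra > 0` appends that many un-amputed rows (the
#' "some complete rows", SCR, condition), `n_complete_extra = 0` is the
#' "no complete rows" (NCR) condition.
#'
#' @param p Number of predictors (at least 5).
#' @param n_train Training rows subjected to amputation.
#' @param n_complete_extra Fully observed rows appended to the training set.
#' @param n_test Fully observed test rows.
#' @param missing_rate Per-predictor MCAR missingness fraction in `[0, 1)`.
#' @param beta Coefficient vector of length `p`; default
#'   `(0.2, 0.3, 0.4, 0, ..., 0)`.
#' @param beta0 True intercept (default 0).
#' @param noise_var Variance of the Gaussian noise term.
#' @param corr_range Interval from which pairwise correlations among
#'   `x1..x5` are drawn uniformly.
#' @param seed Optional RNG seed consumed by [build_scenario()].
#' @return An object of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(p = 20)
#' cfg$beta[1:4]
#' @export
scenario_config <- function(p,
                            n_train = 3150,
                            n_complete_extra = 50,
                            n_test = 1000,
                            missing_rate = 0.8,
                            beta = NULL,
                            beta0 = 0,
                            noise_var = 0.25,
                            corr_range = c(-0.5, 0.5),
                            seed = NULL) {
  if (p < 5) stop("p must be at least 5 (correlated block spans x1..x5)")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (noise_var <= 0) stop("noise_var must be positive")
  if (is.null(beta)) beta <- c(0.2, 0.3, 0.4, rep(0, p - 3))
  if (length(beta) != p) stop("beta must have length p")
  if (length(corr_range) != 2 || corr_range[1] > corr_range[2] ||
      corr_range[1] <= -1 || corr_range[2] >= 1)
    stop("corr_range must be an interval inside (-1, 1)")
  structure(list(p = p, n_train = n_train,
                 n_complete_extra = n_complete_extra, n_test = n_test,
                 missing_rate = missing_rate, beta = beta, beta0 = beta0,
                 noise_var = noise_var, corr_range = corr_range,
                 seed = seed),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> p=%d, train=%d+%d complete, test=%d, %.0f%% MCAR\n",
              x$p, x$n_train, x$n_complete_extra, x$n_test,
              100 * x$missing_rate))
  invisible(x)
}

# Nearest positive-definite repair of a correlation matrix:
# clip eigenvalues at `eps`, reconstruct, rescale to unit diagonal.
near_pd_corr <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > eps) return(R)
  vals <- pmax(e$values, eps)
  A <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(A))
  A <- A / tcrossprod(d)
  diag(A) <- 1
  (A + t(A)) / 2
}

#' Build the random correlation matrix of a scenario
#'
#' Pairs within `x1..x5` receive correlations drawn uniformly from
#' `corr_range`; all other off-diagonal entries are zero. If the raw draw
#' is not positive definite it is repaired by eigenvalue clipping (floor
#' `1e-6`) followed by rescaling to unit diagonal.
#'
#' Uses the current R random number stream.
#'
#' @param config A [scenario_config()].
#' @return A p x p positive-definite correlation matrix.
#' @export
build_correlation_matrix <- function(config) {
  p <- config$p
  R <- diag(p)
  idx <- utils::combn(5L, 2L)
  r <- runif(ncol(idx), config$corr_range[1], config$corr_range[2])
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    R[i, j] <- R[j, i] <- r[k]
  }
  near_pd_corr(R)
}

#' Generate fully observed rows from the scenario model
#'
#' Sampling is by Gaussian copula: a multivariate normal draw with the
#' given correlation matrix is pushed through the standard-normal CDF and
#' then the inverse CDF of each target marginal (`Beta(7,2)`, `U(0,2)`,
#' standard normal for the rest), which honours both the stated marginals
#' and the latent correlation structure. The outcome is the linear model
#' plus `N(0, noise_var)` noise.
#'
#' @param config A [scenario_config()].
#' @param corr Positive-definite correlation matrix from
#'   [build_correlation_matrix()].
#' @param n_rows Number of rows to generate.
#' @return A complete [tabular_dataset()].
#' @export
generate_complete_data <- function(config, corr, n_rows) {
  p <- config$p
  ch <- tryCatch(chol(corr),
                 error = function(e) stop("correlation matrix is not positive definite"))
  Z <- matrix(rnorm(n_rows * p), n_rows, p) %*% ch
  X <- Z
  X[, 1] <- qbeta(pnorm(Z[, 1]), 7, 2)
  X[, 2] <- qunif(pnorm(Z[, 2]), 0, 2)
  colnames(X) <- paste0("x", seq_len(p))
  y <- config$beta0 + drop(X %*% config$beta) +
    rnorm(n_rows, 0, sqrt(config$noise_var))
  tabular_dataset(y, X)
}

#' Remove values completely at random
#'
#' Each predictor cell is independently set missing with probability
#' `missing_rate`; the outcome is never touched.
#'
#' @param data A fully observed [tabular_dataset()].
#' @param missing_rate Probability in `[0, 1)` that a cell is removed.
#' @return A `tabular_dataset` with updated predictors and mask.
#' @export
ampute_mcar <- function(data, missing_rate) {
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  if (any(data$mask == 0L)) stop("ampute_mcar expects fully observed data")
  X <- data$predictors
  drop_mask <- matrix(runif(length(X)) < missing_rate, nrow(X), ncol(X))
  X[drop_mask] <- NA_real_
  tabular_dataset(data$outcome, X, outcome_name = data$outcome_name)
}

#' Assemble one train/test scenario replicate
#'
#' Draws the random correlation matrix, generates and amputes `n_train`
#' training rows, appends `n_complete_extra` fresh fully observed rows
#' (SCR) or none (NCR), and generates a fully observed test set. All draws
#' are reproducible from `seed`.
#'
#' @param config A [scenario_config()].
#' @param seed Optional integer seed; defaults to `config$seed`.
#' @return List with elements `train`, `test` (both `tabular_dataset`) and
#'   `corr` (the correlation matrix used).
#' @examples
#' sc <- build_scenario(scenario_config(p = 5, n_train = 40,
#'                                      n_complete_extra = 4, n_test = 10),
#'                      seed = 1)
#' print(sc$train)
#' @export
build_scenario <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  corr <- build_correlation_matrix(config)
  train <- ampute_mcar(generate_complete_data(config, corr, config$n_train),
                       config$missing_rate)
  if (config$n_complete_extra > 0) {
    extra <- generate_complete_data(config, corr, config$n_complete_extra)
    train <- tabular_dataset(c(train$outcome, extra$outcome),
                             rbind(train$predictors, extra$predictors),
                             outcome_name = train$outcome_name)
  }
  test <- generate_complete_data(config, corr, config$n_test)
  list(train = train, test = test, corr = corr)
}
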