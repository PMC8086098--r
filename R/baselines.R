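#' Mean imputation
#'
#' Fills every missing cell with the column mean of the observed values.
#' This is the normalising baseline of the benchmark: all reported MSE
#' ratios are relative to a linear model fitted after mean imputation.
#'
#' @param data A [tabular_dataset()].
#' @return A complete `tabular_dataset`; observed cells are untouched.
#' @export
mean_impute <- function(data) {
  X <- data$predictors
  for (j in seq_len(ncol(X))) {
    obs <- !is.na(X[, j])
    if (!any(obs))
      stop("column '", colnames(X)[j], "' has no observed values")
    X[!obs, j] <- mean(X[obs, j])
  }
  tabular_dataset(data$outcome, X, outcome_name = data$outcome_name)
}

#' Complete-case (simple linear) regression
#'
#' Ordinary least squares on the fully observed rows only. With fewer
#' than `p + 2` complete rows the fit is infeasible and a structured
#' error is raised — this is why the complete-case baseline is absent in
#' scenarios without complete training rows.
#'
#' @param data A [tabular_dataset()].
#' @return An object of class `cca_model` wrapping the `lm` fit.
#' @export
cca_regress <- function(data) {
  idx <- complete_rows(data)
  p <- n_predictors(data)
  if (length(idx) < p + 2)
    dmu_infeasible(sprintf(
      "complete-case regression needs at least p + 2 = %d complete rows, found %d",
      p + 2, length(idx)))
  df <- data.frame(.y = data$outcome[idx],
                   data$predictors[idx, , drop = FALSE],
                   check.names = FALSE)
  fit <- lm(.y ~ ., data = df)
  structure(list(fit = fit, schema = data$column_names,
                 n_complete = length(idx)),
            class = "cca_model")
}

#' @export
print.cca_model <- function(x, ...) {
  cat(sprintf("<cca_model> OLS on %d complete rows, %d predictors\n",
              x$n_complete, length(x$schema)))
  print(coef(x$fit))
  invisible(x)
}

#' @export
predict.cca_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "tabular_dataset")) newdata$predictors else
    as.matrix(newdata)
  unname(predict(object$fit,
                 newdata = as.data.frame(X[, object$schema, drop = FALSE])))
}

# Pick one donor per missing cell: among the k observed cells whose
# predictions are closest to the missing cell's prediction (absolute
# difference; ties broken by original row index), copy a random donor's
# observed value.
pmm_match <- function(pred_mis, pred_obs, obs_values, k_donors) {
  ord <- order(pred_obs, seq_along(pred_obs))
  ps <- pred_obs[ord]; vs <- obs_values[ord]; orig <- ord
  n_obs <- length(ps)
  pos <- findInterval(pred_mis, ps)
  out <- numeric(length(pred_mis))
  for (i in seq_along(pred_mis)) {
    lo <- max(1L, pos[i] - k_donors + 1L)
    hi <- min(n_obs, pos[i] + k_donors)
    cand <- lo:hi
    d <- abs(ps[cand] - pred_mis[i])
    keep <- cand[order(d, orig[cand])][seq_len(min(k_donors, length(cand)))]
    out[i] <- vs[keep[sample.int(length(keep), 1L)]]
  }
  out
}

#' Predictive-mean-matching multiple imputation
#'
#' Chained-equations PMM: cycling over the incomplete columns, each is
#' regressed on the outcome and the other predictors (their current
#' completions); each missing cell receives the *observed* value of one
#' of the `k_donors` rows whose predictions are closest to its own, drawn
#' at random. `n_cycles` sweeps produce one completed table; `m`
#' independent repetitions give the multiple imputations. A degenerate
#' regression falls back to a random observed donor with a warning.
#'
#' @param data A [tabular_dataset()].
#' @param m Number of completed tables (default 5).
#' @param k_donors Donor-pool size (default 5).
#' @param n_cycles Chained-equation sweeps per table (default 5).
#' @param include_outcome If `TRUE`, the outcome joins the predictors in
#'   each imputation model (the usual multiple-imputation convention);
#'   default `FALSE` imputes from the other predictor columns only.
#' @param seed Optional RNG seed.
#' @return An object of class `imputed_datasets`: list of `m` complete
#'   `tabular_dataset`s plus the method label.
#' @export
pmm_impute <- function(data, m = 5, k_donors = 5, n_cycles = 5,
                       include_outcome = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X0 <- data$predictors
  obs_mask <- !is.na(X0)
  if (any(colSums(obs_mask) < k_donors))
    stop("every column needs at least k_donors = ", k_donors,
         " observed values")
  incomplete <- which(colSums(!obs_mask) > 0L)
  base_fill <- mean_impute(data)$predictors

  impute_once <- function() {
    X <- base_fill
    for (cycle in seq_len(n_cycles)) {
      for (j in incomplete) {
        obs <- obs_mask[, j]
        design <- if (include_outcome)
          cbind(1, data$outcome, X[, -j, drop = FALSE])
        else cbind(1, X[, -j, drop = FALSE])
        pred <- tryCatch({
          cf <- lm.fit(design[obs, , drop = FALSE], X0[obs, j])$coefficients
          ok <- !is.na(cf)
          if (!any(ok)) stop("no estimable coefficient")
          drop(design[, ok, drop = FALSE] %*% cf[ok])
        }, error = function(e) {
          warning("degenerate regression for column '", colnames(X0)[j],
                  "'; falling back to random donors")
          NULL
        })
        X[!obs, j] <- if (is.null(pred)) {
          sample(X0[obs, j], sum(!obs), replace = TRUE)
        } else {
          pmm_match(pred[!obs], pred[obs], X0[obs, j], k_donors)
        }
      }
    }
    tabular_dataset(data$outcome, X, outcome_name = data$outcome_name)
  }

  structure(list(datasets = lapply(seq_len(m), function(i) impute_once()),
                 method = "pmm", m = as.integer(m),
                 k_donors = as.integer(k_donors),
                 n_cycles = as.integer(n_cycles)),
            class = "imputed_datasets")
}

#' @export
print.imputed_datasets <- function(x, ...) {
  cat(sprintf("<imputed_datasets> %d completed tables (%s)\n", x$m, x$method))
  invisible(x)
}

#' Pooled linear regression over multiple imputations
#'
#' Fits OLS on each completed table and pools with Rubin's rules: pooled
#' coefficients are the mean of the per-imputation estimates; the total
#' variance decomposes as `within + (1 + 1/m) * between`, where `within`
#' is the mean squared standard error and `between` the variance of the
#' estimates across imputations.
#'
#' @param imp An [pmm_impute()] result (or any `imputed_datasets`).
#' @return An object of class `pooled_model` with `coefficients`,
#'   `within_var`, `between_var`, `total_var` and `m`.
#' @export
pooled_regress <- function(imp) {
  m <- imp$m
  fits <- lapply(imp$datasets, function(d) {
    df <- data.frame(.y = d$outcome, d$predictors, check.names = FALSE)
    fit <- lm(.y ~ ., data = df)
    if (anyNA(coef(fit)))
      stop("rank-deficient fit in one imputation: ",
           paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
    fit
  })
  est <- vapply(fits, coef, numeric(length(coef(fits[[1]]))))
  se2 <- vapply(fits, function(f) diag(vcov(f)), numeric(nrow(est)))
  pooled <- rowMeans(est)
  within <- rowMeans(se2)
  between <- if (m >= 2) apply(est, 1L, var) else rep(NA_real_, nrow(est))
  structure(list(coefficients = pooled, within_var = within,
                 between_var = between,
                 total_var = within + (1 + 1 / m) * between,
                 m = m, schema = imp$datasets[[1]]$column_names),
            class = "pooled_model")
}

#' @export
print.pooled_model <- function(x, ...) {
  cat(sprintf("<pooled_model> OLS pooled over %d imputations\n", x$m))
  print(data.frame(estimate = x$coefficients,
                   total_se = sqrt(x$total_var)))
  invisible(x)
}

#' @export
predict.pooled_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "tabular_dataset")) newdata$predictors else
    as.matrix(newdata)
  X <- X[, object$schema, drop = FALSE]
  b <- object$coefficients
  unname(b[1L] + drop(X %*% b[-1L]))
}
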