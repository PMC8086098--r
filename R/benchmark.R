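#' Run every method on one simulated replicate
#'
#' Generates one train/test pair from the scenario configuration and
#' evaluates each requested method's test mean-squared error on the shared
#' pair. Methods: `"mean"` (mean imputation + OLS), `"slr"` (complete-case
#' OLS), `"slrm"` (chained PMM multiple imputation + Rubin-pooled OLS),
#' `"dmu"` (missingness clustering + sequential Bayesian updating with
#' GA-selected subgroup count), plus any user-supplied imputers. A method
#' that is infeasible for the scenario (complete-case OLS without enough
#' complete rows) is recorded as `NA`, not an error.
#'
#' @param config A [scenario_config()].
#' @param methods Character vector of built-in method names.
#' @param seed Master seed for the replicate; the scenario draw, PMM, GA
#'   and MCMC streams are derived from it.
#' @param mcmc An [mcmc_config()] for the DMU fits.
#' @param ga A [ga_config()] for subgroup-count selection.
#' @param min_ratio,linkage,metric Fragmentation/clustering settings.
#' @param fitness_on_test If `TRUE`, the GA fitness is scored on the test
#'   table (the benchmark-parity protocol); default `FALSE` holds out
#'   `ga$fitness_holdout` of the training rows instead.
#' @param imputers Named list of functions `function(train)` returning a
#'   complete `tabular_dataset`; each is followed by OLS and scored like
#'   the built-ins (pluggable third-party imputation baselines).
#' @return List with `mse` (named numeric; `NA` = infeasible), `details`
#'   (per-method extras such as the selected `k`) and `seed`.
#' @export
run_replicate <- function(config, methods = c("mean", "slr", "slrm", "dmu"),
                          seed = 1, mcmc = mcmc_config(), ga = ga_config(),
                          min_ratio = 2, linkage = "complete",
                          metric = "euclidean", fitness_on_test = FALSE,
                          imputers = list()) {
  known <- c("mean", "slr", "slrm", "dmu")
  if (length(bad <- setdiff(methods, known)))
    stop("unknown methods: ", paste(bad, collapse = ", "))
  sc <- build_scenario(config, seed = seed)
  train <- sc$train; test <- sc$test
  mse_of <- function(model) mean((test$outcome - predict(model, test))^2)

  mse <- c(); details <- list()
  run <- function(name, fn) {
    out <- tryCatch(fn(), dmu_infeasible_error = function(e) {
      details[[name]] <<- list(infeasible = conditionMessage(e))
      NA_real_
    })
    mse[[name]] <<- out
  }

  for (m in methods) {
    switch(m,
      mean = run("mean", function() mse_of(cca_regress(mean_impute(train)))),
      slr = run("slr", function() mse_of(cca_regress(train))),
      slrm = run("slrm", function() {
        imp <- pmm_impute(train, seed = seed + 1013L)
        mse_of(pooled_regress(imp))
      }),
      dmu = run("dmu", function() {
        ga_run <- ga
        ga_run$seed <- seed + 2029L
        if (fitness_on_test) {
          fit_train <- train; holdout <- test
        } else {
          set.seed(seed + 3047L)
          hold_idx <- sample.int(n_rows(train),
                                 max(2L, floor(ga$fitness_holdout *
                                                 n_rows(train))))
          fit_train <- dataset_rows(train, -hold_idx)
          holdout <- dataset_rows(train, hold_idx)
        }
        mcmc_run <- mcmc_config(mcmc$n_iter, mcmc$burn_in)
        sel <- select_k_ga(fit_train, holdout, ga = ga_run,
                           min_ratio = min_ratio, linkage = linkage,
                           metric = metric, mcmc = mcmc_run,
                           seed = seed + 4057L)
        model <- if (fitness_on_test) {
          # parity protocol: the best model found by the search IS the
          # selected final model
          sel$model
        } else {
          # selection used a holdout; refit on the full training table
          bin <- binarize_missingness(train)
          cl <- cluster_rows(bin, min(sel$best_k, n_rows(train)),
                             linkage = linkage, metric = metric)
          frag <- fragment(train, cl, min_ratio = min_ratio)
          if (!length(frag$subdatasets))
            dmu_infeasible("no usable fragment at the selected k")
          mcmc_run$seed <- seed + 5077L
          dmu_fit(frag, mcmc = mcmc_run)
        }
        details$dmu <<- list(best_k = sel$best_k,
                             best_fitness = sel$best_fitness)
        mse_of(model)
      }))
  }
  for (nm in names(imputers)) {
    fn <- imputers[[nm]]
    run(nm, function() mse_of(cca_regress(fn(train))))
  }
  list(mse = unlist(mse), details = details, seed = seed)
}

#' Summarize replicate MSEs into normalized benchmark ratios
#'
#' For each replicate, every method's MSE is divided by that replicate's
#' mean-imputation MSE; the summary reports the mean ratio and a
#' normal-approximation 95% confidence interval (`mean +/- 1.96 * SE`)
#' across replicates. Replicates where a method was infeasible are
#' dropped for that method only.
#'
#' @param replicates List of [run_replicate()] results (length `S >= 2`).
#' @return An object of class `benchmark_result` with `ratios` (method x
#'   replicate matrix) and `summary` (data frame with mean and CI).
#' @export
summarize_benchmark <- function(replicates) {
  if (length(replicates) < 2L) stop("need at least S = 2 replicates")
  meth <- unique(unlist(lapply(replicates, function(r) names(r$mse))))
  if (!"mean" %in% meth)
    stop("mean-imputation MSE is the normalizer and must be present")
  ratios <- vapply(replicates, function(r) {
    if (!is.finite(r$mse[["mean"]]))
      stop("mean-imputation MSE missing in a replicate")
    r$mse[meth] / r$mse[["mean"]]
  }, numeric(length(meth)))
  ratios <- matrix(ratios, nrow = length(meth),
                   dimnames = list(meth, NULL))
  summ <- do.call(rbind, lapply(meth, function(m) {
    x <- ratios[m, ]
    x <- x[is.finite(x)]
    if (!length(x))
      return(data.frame(method = m, mean_ratio = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n = 0L))
    se <- if (length(x) > 1L) sd(x) / sqrt(length(x)) else NA_real_
    data.frame(method = m, mean_ratio = mean(x),
               ci_low = mean(x) - 1.96 * se, ci_high = mean(x) + 1.96 * se,
               n = length(x))
  }))
  structure(list(ratios = ratios, summary = summ, S = length(replicates)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> S = %d replicates; MSE ratios vs mean imputation\n",
              x$S))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Run the full simulation benchmark for one scenario
#'
#' Repeats [run_replicate()] for `S` independent replicates (each redraws
#' the random correlation matrix) with seeds derived from the master seed
#' by replicate index, then normalizes by the mean-imputation baseline.
#'
#' @param config A [scenario_config()].
#' @param S Number of replicates.
#' @param seed Master seed.
#' @param ... Passed on to [run_replicate()].
#' @inheritParams run_replicate
#' @return A `benchmark_result`; its `replicates` element keeps the raw
#'   per-replicate MSEs.
#' @export
run_benchmark <- function(config, S = 30, methods = c("mean", "slr",
                                                      "slrm", "dmu"),
                          seed = 1, ...) {
  reps <- lapply(seq_len(S), function(i)
    run_replicate(config, methods = methods,
                  seed = (seed + 104729L * i) %% 2147483647L, ...))
  out <- summarize_benchmark(reps)
  out$replicates <- reps
  out
}
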