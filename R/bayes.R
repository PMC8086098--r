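#' MCMC settings for the Gibbs sampler
#'
#' @param n_iter Total Gibbs iterations (default 6000).
#' @param burn_in Initial iterations discarded (default 1000).
#' @param seed Optional RNG seed consumed by [dmu_fit()] / [gibbs_fit()].
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 6000, burn_in = 1000, seed = NULL) {
  if (burn_in < 0 || burn_in >= n_iter)
    stop("need 0 <= burn_in < n_iter")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 seed = seed),
            class = "mcmc_config")
}

#' Initial coefficient and precision beliefs
#'
#' The prior of the first fitted fragment: every coefficient (including
#' the intercept, stored under `"(Intercept)"`) is `N(coef_mean, coef_var)`
#' and the noise precision is `Gamma(prec_shape, prec_rate)`; the defaults
#' are `N(0, 100)` and `Gamma(5/2, 50/2)`. After each fragment the matching
#' entries are overwritten by moment-matched posterior summaries, so the
#' state always holds the current belief about every coefficient of the
#' full schema.
#'
#' @param column_names Predictor names of the full training schema.
#' @param coef_mean,coef_var Prior mean/variance of every coefficient.
#' @param prec_shape,prec_rate Gamma prior on the noise precision.
#' @return An object of class `belief_state`: named vectors `mean` and
#'   `variance`, a `precision` (shape, rate) pair and an empty `history`.
#' @export
belief_state <- function(column_names, coef_mean = 0, coef_var = 100,
                         prec_shape = 5 / 2, prec_rate = 50 / 2) {
  if (coef_var <= 0) stop("coefficient prior variance must be positive")
  if (prec_shape <= 0 || prec_rate <= 0)
    stop("precision prior shape and rate must be positive")
  ids <- c(.intercept, column_names)
  structure(list(mean = stats::setNames(rep(coef_mean, length(ids)), ids),
                 variance = stats::setNames(rep(coef_var, length(ids)), ids),
                 precision = c(shape = prec_shape, rate = prec_rate),
                 history = list()),
            class = "belief_state")
}

#' @export
print.belief_state <- function(x, ...) {
  cat(sprintf("<belief_state> %d coefficients, precision Gamma(%.3g, %.3g), %d updates\n",
              length(x$mean), x$precision["shape"], x$precision["rate"],
              length(x$history)))
  df <- data.frame(mean = x$mean, variance = x$variance)
  print(utils::head(df, 8L))
  if (length(x$mean) > 8L) cat("...\n")
  invisible(x)
}

#' Gibbs-sample the Bayesian regression posterior of one sub-dataset
#'
#' Semi-conjugate sampler: the coefficient block is drawn from its
#' multivariate normal full conditional given the noise precision (with
#' independent normal priors per coefficient), the precision from its
#' gamma full conditional given the coefficients. Draws after `burn_in`
#' are retained. Deterministic given the R random seed.
#'
#' @param sub A `sub_dataset` from [fragment()] (or anything with
#'   `outcome`, `predictors`, `predictor_subset`).
#' @param prior A [belief_state()]; only the entries for the intercept and
#'   `sub`'s predictors are used.
#' @param mcmc An [mcmc_config()].
#' @return An object of class `dmu_draws`: `beta` (retained draws, one
#'   column per coefficient) and `tau` (precision draws).
#' @export
gibbs_fit <- function(sub, prior, mcmc = mcmc_config()) {
  X <- cbind(1, sub$predictors)
  ids <- c(.intercept, sub$predictor_subset)
  colnames(X) <- ids
  if (anyNA(X) || anyNA(sub$outcome))
    stop("sub-dataset must be fully observed")
  if (qr(X)$rank < ncol(X))
    stop(structure(
      class = c("dmu_singular_error", "error", "condition"),
      list(message = paste0(
        "singular design in sub-dataset (predictors collinear after ",
        "fragmentation); consider a larger min_ratio so fragments carry ",
        "more rows per predictor"), call = sys.call(-1))))
  m0 <- prior$mean[ids]
  v0 <- prior$variance[ids]
  if (anyNA(m0) || anyNA(v0))
    stop("prior does not cover columns: ",
         paste(ids[is.na(m0) | is.na(v0)], collapse = ", "))
  if (any(v0 <= 0)) stop("prior variances must be positive")
  if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
  out <- gibbs_chain_cpp(X, sub$outcome, unname(m0), unname(v0),
                         prior$precision[["shape"]],
                         prior$precision[["rate"]],
                         mcmc$n_iter, mcmc$burn_in)
  colnames(out$beta) <- ids
  structure(out, class = "dmu_draws")
}

#' Moment-matched belief summaries of posterior draws
#'
#' Coefficient beliefs are the marginal sample mean and variance of each
#' coefficient's retained draws (posterior correlations between
#' coefficients are deliberately dropped so the belief stays in the
#' independent-normal prior family). The precision belief is a gamma
#' matched by method of moments (`shape = mean^2/var`, `rate = mean/var`).
#' Variances are floored at `1e-10` (with a warning) to keep subsequent
#' priors proper.
#'
#' @param draws A [gibbs_fit()] result with at least 100 retained draws.
#' @return List with `mean`, `variance` (named by coefficient) and
#'   `precision` (shape, rate).
#' @export
summarize_posterior <- function(draws) {
  if (nrow(draws$beta) < 100L)
    stop("need at least 100 retained draws to summarize a posterior")
  m <- colMeans(draws$beta)
  v <- apply(draws$beta, 2L, var)
  if (any(v < 1e-10)) {
    warning("posterior variance floored at 1e-10 for: ",
            paste(names(v)[v < 1e-10], collapse = ", "))
    v <- pmax(v, 1e-10)
  }
  tm <- mean(draws$tau); tv <- var(draws$tau)
  if (!is.finite(tv) || tv <= 0)
    stop("zero-variance precision draws: sampler failure")
  list(mean = m, variance = v,
       precision = c(shape = tm^2 / tv, rate = tm / tv))
}

#' Fit the dynamic-model-updating chain over a fragmentation
#'
#' Iterates the sub-datasets in fragmentation order. For each one, the
#' current beliefs of the columns present in that fragment (plus the
#' intercept) serve as the prior of a Gibbs-sampled Bayesian regression;
#' the moment-matched posterior then overwrites exactly those beliefs.
#' Columns absent from a fragment are untouched, so a predictor never
#' observed jointly with others simply keeps its prior.
#'
#' @param frag A [fragment()] result.
#' @param init Initial [belief_state()]; default `N(0, 100)` coefficients
#'   and `Gamma(5/2, 50/2)` precision over `frag$schema`.
#' @param mcmc An [mcmc_config()]; its `seed` (if any) is set once before
#'   the chain starts.
#' @param chain_precision If `TRUE` (default) the gamma precision belief
#'   is also carried across fragments; if `FALSE` it is reset to the
#'   initial prior for every fragment.
#' @param center If `TRUE` (default) every fragment's predictors are
#'   centred at the global observed-cell column means recorded by
#'   [fragment()]. Different fragments carry different predictor subsets;
#'   without centring each fragment's intercept absorbs the mean
#'   contribution of whichever predictors it lacks, so the chained
#'   intercept belief mixes incompatible quantities. Centring makes every
#'   fragment estimate the same intercept (the overall outcome mean).
#'   Predictions translate back automatically.
#' @return An object of class `dmu_model`: the final belief state plus a
#'   per-fragment `history` and the training `schema`.
#' @export
dmu_fit <- function(frag, init = NULL, mcmc = mcmc_config(),
                    chain_precision = TRUE, center = TRUE) {
  if (is.null(init)) init <- belief_state(frag$schema)
  state <- init
  centers <- if (center && !is.null(frag$col_center)) frag$col_center else
    stats::setNames(rep(0, length(frag$schema)), frag$schema)
  if (!length(frag$subdatasets)) {
    warning("empty fragmentation: returning the initial beliefs unchanged")
  } else {
    if (!is.null(mcmc$seed)) set.seed(mcmc$seed)
    mcmc_nested <- mcmc_config(mcmc$n_iter, mcmc$burn_in) # seed handled here
    for (i in seq_along(frag$subdatasets)) {
      sub <- frag$subdatasets[[i]]
      sub$predictors <- sweep(sub$predictors, 2L,
                              centers[sub$predictor_subset])
      draws <- gibbs_fit(sub, state, mcmc_nested)
      post <- summarize_posterior(draws)
      state$mean[names(post$mean)] <- post$mean
      state$variance[names(post$variance)] <- post$variance
      if (chain_precision) state$precision <- post$precision
      state$history[[i]] <- list(index = i,
                                 n_rows = length(sub$row_ids),
                                 predictors = sub$predictor_subset,
                                 mean = post$mean,
                                 variance = post$variance,
                                 precision = post$precision)
    }
  }
  structure(list(mean = state$mean, variance = state$variance,
                 precision = state$precision, history = state$history,
                 schema = frag$schema, center = centers),
            class = "dmu_model")
}

#' @export
print.dmu_model <- function(x, ...) {
  cat(sprintf("<dmu_model> %d coefficients, %d fragments fitted\n",
              length(x$mean), length(x$history)))
  nz <- order(-abs(x$mean))[seq_len(min(6L, length(x$mean)))]
  print(data.frame(mean = x$mean[nz], sd = sqrt(x$variance[nz])))
  invisible(x)
}

#' Predict outcomes from a fitted DMU model
#'
#' Plug-in prediction with posterior coefficient means:
#' `yhat = mean[(Intercept)] + sum_j mean_j x_j`.
#'
#' @param object A [dmu_fit()] result.
#' @param newdata A fully observed [tabular_dataset()] (or numeric matrix
#'   with the training columns).
#' @param variance If `TRUE`, also return the coefficient-uncertainty and
#'   noise contributions to the predictive variance.
#' @param ... Unused.
#' @return Numeric vector of predictions (or a list when
#'   `variance = TRUE`).
#' @export
predict.dmu_model <- function(object, newdata, variance = FALSE, ...) {
  X <- if (inherits(newdata, "tabular_dataset")) newdata$predictors else
    as.matrix(newdata)
  if (!all(object$schema %in% colnames(X)))
    stop("newdata lacks training columns: ",
         paste(setdiff(object$schema, colnames(X)), collapse = ", "))
  X <- X[, object$schema, drop = FALSE]
  if (anyNA(X)) stop("newdata must be fully observed")
  if (!is.null(object$center))
    X <- sweep(X, 2L, object$center[object$schema])
  yhat <- object$mean[[.intercept]] + drop(X %*% object$mean[object$schema])
  if (!variance) return(yhat)
  coef_var <- object$variance[[.intercept]] +
    drop(X^2 %*% object$variance[object$schema])
  noise_var <- object$precision[["rate"]] / object$precision[["shape"]]
  list(fit = yhat, coef_var = coef_var, noise_var = noise_var)
}

#' Serialize a DMU model to JSON
#'
#' Full-precision JSON (coefficient means/variances, precision belief,
#' fragment history); [read_model()] restores an equivalent model.
#'
#' @param model A `dmu_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(
    format = "dmu-model",
    version = 1L,
    schema = model$schema,
    coefficients = lapply(stats::setNames(nm = names(model$mean)), function(id)
      list(mean = model$mean[[id]], variance = model$variance[[id]])),
    center = as.list(model$center),
    precision = as.list(model$precision),
    history = lapply(model$history, function(h)
      list(index = h$index, n_rows = h$n_rows, predictors = I(h$predictors))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path)
  if (!identical(p$format, "dmu-model")) stop("not a dmu model file: ", path)
  ids <- names(p$coefficients)
  structure(list(
    mean = vapply(p$coefficients, function(z) z$mean, numeric(1)),
    variance = vapply(p$coefficients, function(z) z$variance, numeric(1)),
    center = unlist(p$center),
    precision = c(shape = p$precision$shape, rate = p$precision$rate),
    history = lapply(p$history, function(h)
      list(index = h$index, n_rows = h$n_rows,
           predictors = unlist(h$predictors))),
    schema = setdiff(ids, .intercept)),
    class = "dmu_model")
}
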