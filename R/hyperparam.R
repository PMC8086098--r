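#' Genetic-algorithm settings for subgroup-count selection
#'
#' @param k_min,k_max Search bounds on the number of subgroups; `k_max`
#'   defaults (at use time) to the number of training rows.
#' @param pop_size Population size (default 20).
#' @param n_generations Number of generations (default 15); 0 evaluates
#'   only the initial population.
#' @param crossover_prob Probability of single-point crossover (default 0.8).
#' @param mutation_prob Per-bit flip probability (default 0.1).
#' @param elitism_count Best individuals copied unchanged (default 2).
#' @param seed Optional RNG seed.
#' @param fitness_holdout Fraction of training rows held out to score
#'   fitness when no external holdout table is supplied (default 0.2).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(k_min = 1, k_max = NULL, pop_size = 20,
                      n_generations = 15, crossover_prob = 0.8,
                      mutation_prob = 0.1, elitism_count = 2,
                      seed = NULL, fitness_holdout = 0.2) {
  if (k_min < 1) stop("k_min must be at least 1")
  if (!is.null(k_max) && k_max < k_min) stop("need k_min <= k_max")
  for (pr in c(crossover_prob, mutation_prob))
    if (pr < 0 || pr > 1) stop("probabilities must lie in [0, 1]")
  structure(list(k_min = as.integer(k_min),
                 k_max = if (is.null(k_max)) NULL else as.integer(k_max),
                 pop_size = as.integer(pop_size),
                 n_generations = as.integer(n_generations),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 elitism_count = as.integer(elitism_count),
                 seed = seed, fitness_holdout = fitness_holdout),
            class = "ga_config")
}

# Shared evaluation context: binary matrix and linkage tree built once,
# fitness values (and fitted models) memoized per k.
fitness_context <- function(train, holdout, min_ratio = 2,
                            linkage = "complete", metric = "euclidean",
                            mcmc = mcmc_config(), seed = NULL) {
  bin <- binarize_missingness(train)
  holdout_X <- holdout$predictors
  if (anyNA(holdout_X))   # fitness rows may carry missing cells: fill by
    holdout_X <- mean_impute(holdout)$predictors  # column means for scoring
  list(train = train, bin = bin,
       tree = missingness_linkage(bin, linkage, metric),
       holdout_y = holdout$outcome, holdout_X = holdout_X,
       min_ratio = min_ratio, mcmc = mcmc, seed = seed,
       cache = new.env(parent = emptyenv()))
}

eval_fitness <- function(ctx, k) {
  key <- as.character(k)
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit$fitness)
  if (!is.null(ctx$seed))
    set.seed((ctx$seed + 7919 * k) %% 2147483647L)
  cl <- cluster_rows(ctx$bin, k, tree = ctx$tree)
  frag <- fragment(ctx$train, cl, min_ratio = ctx$min_ratio)
  res <- if (!length(frag$subdatasets)) {
    list(fitness = Inf, model = NULL)   # infeasible k: sentinel, not error
  } else {
    # a k whose fragments have singular designs is infeasible, not fatal
    model <- tryCatch(dmu_fit(frag, mcmc = ctx$mcmc),
                      dmu_singular_error = function(e) NULL)
    if (is.null(model)) list(fitness = Inf, model = NULL) else {
      yhat <- predict(model, ctx$holdout_X)
      list(fitness = sqrt(mean((ctx$holdout_y - yhat)^2)), model = model)
    }
  }
  ctx$cache[[key]] <- res
  res$fitness
}

#' Holdout RMSE of the DMU pipeline at a given subgroup count
#'
#' Clusters the training rows at `k`, fragments, fits the sequential
#' Bayesian chain and scores root-mean-square error on the holdout table.
#' Infeasible `k` (no fragment survives the usability constraint) yields
#' `Inf` rather than an error. Holdout rows with missing predictors are
#' completed by column means for scoring only.
#'
#' @param k Number of subgroups, `1 <= k <=` training rows.
#' @param train Training [tabular_dataset()].
#' @param holdout Fully (or partially) observed scoring table.
#' @param min_ratio,linkage,metric,mcmc,seed Pipeline settings; see
#'   [fragment()], [cluster_rows()], [mcmc_config()].
#' @return RMSE (numeric scalar, possibly `Inf`).
#' @export
k_fitness <- function(k, train, holdout, min_ratio = 2,
                      linkage = "complete", metric = "euclidean",
                      mcmc = mcmc_config(), seed = NULL) {
  ctx <- fitness_context(train, holdout, min_ratio, linkage, metric,
                         mcmc, seed)
  eval_fitness(ctx, k)
}

ga_result <- function(best_k, best_fitness, trace, evaluations, method) {
  structure(list(best_k = as.integer(best_k), best_fitness = best_fitness,
                 trace = trace, evaluations = evaluations, method = method),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf("<ga_result> %s search: best k = %d (RMSE %.4g), %d evaluations\n",
              x$method, x$best_k, x$best_fitness, nrow(x$evaluations)))
  invisible(x)
}

collect_evaluations <- function(ctx) {
  ks <- sort(as.integer(ls(ctx$cache)))
  data.frame(k = ks,
             fitness = vapply(as.character(ks),
                              function(key) ctx$cache[[key]]$fitness,
                              numeric(1)))
}

best_model_from <- function(ctx, k) {
  hit <- ctx$cache[[as.character(k)]]
  if (is.null(hit)) NULL else hit$model
}

#' Exhaustive sweep over subgroup counts
#'
#' Evaluates [k_fitness()] at every value of `k_range` and returns the
#' argmin; ties break toward the smallest `k` (the cheapest model).
#'
#' @param train,holdout As in [k_fitness()].
#' @param k_range Integer vector of candidate subgroup counts.
#' @param ... Passed to the fitness pipeline ([k_fitness()] settings).
#' @param fitness_fn Optional replacement fitness `function(k)`; used for
#'   algorithm testing with synthetic fitness landscapes.
#' @return A `ga_result` (with `method = "exhaustive"`); its `model`
#'   element holds the fitted model at `best_k` when the internal fitness
#'   was used.
#' @export
select_k_exhaustive <- function(train, holdout, k_range, ...,
                                fitness_fn = NULL) {
  ctx <- NULL
  if (is.null(fitness_fn)) {
    ctx <- fitness_context(train, holdout, ...)
    fitness_fn <- function(k) eval_fitness(ctx, k)
  }
  k_range <- sort(unique(as.integer(k_range)))
  fit <- vapply(k_range, fitness_fn, numeric(1))
  if (!any(is.finite(fit)))
    stop("no feasible k in the searched range ",
         "(no fragmentation satisfies the usability constraint)")
  best <- k_range[which.min(fit)]   # which.min takes the first = smallest k
  out <- ga_result(best, min(fit),
                   trace = data.frame(generation = 0L, k = k_range,
                                      fitness = fit),
                   evaluations = data.frame(k = k_range, fitness = fit),
                   method = "exhaustive")
  if (!is.null(ctx)) out$model <- best_model_from(ctx, best)
  out
}

#' Genetic-algorithm search over subgroup counts
#'
#' Integer GA on the binary encoding of `k - k_min`: tournament selection
#' (size 2), single-point crossover, per-bit mutation and elitism, with
#' every fitness evaluation memoized per `k`. Decoded values beyond the
#' range wrap around so all chromosomes stay feasible. Deterministic
#' given `ga$seed`.
#'
#' @param train,holdout As in [k_fitness()].
#' @param ga A [ga_config()]; `k_max = NULL` means the number of training
#'   rows.
#' @param ... Passed to the fitness pipeline ([k_fitness()] settings).
#' @param fitness_fn Optional replacement fitness `function(k)` for
#'   testing on synthetic landscapes.
#' @return A `ga_result` with per-generation `trace`, the memoized
#'   `evaluations`, and (for the internal fitness) the fitted `model` at
#'   `best_k`.
#' @export
select_k_ga <- function(train, holdout, ga = ga_config(), ...,
                        fitness_fn = NULL) {
  k_min <- ga$k_min
  k_max <- if (is.null(ga$k_max)) n_rows(train) else ga$k_max
  if (k_max < k_min) stop("need k_min <= k_max")
  range_size <- k_max - k_min + 1L
  n_bits <- max(1L, ceiling(log2(range_size)))

  ctx <- NULL
  if (is.null(fitness_fn)) {
    ctx <- fitness_context(train, holdout, ...)
    fitness_fn <- function(k) eval_fitness(ctx, k)
  }
  memo <- new.env(parent = emptyenv())
  fit_of <- function(k) {
    key <- as.character(k)
    if (is.null(memo[[key]])) memo[[key]] <- fitness_fn(k)
    memo[[key]]
  }
  decode <- function(chrom) {
    v <- sum(chrom * 2^(seq_len(n_bits) - 1L))
    as.integer(k_min + (v %% range_size))
  }
  encode <- function(k) as.integer(intToBits(k - k_min))[seq_len(n_bits)]

  if (!is.null(ga$seed)) set.seed(ga$seed)
  pop <- if (ga$pop_size >= range_size) {
    ks <- c(k_min:k_max,
            sample(k_min:k_max, ga$pop_size - range_size, replace = TRUE))
    lapply(ks, encode)
  } else {
    lapply(sample(k_min:k_max, ga$pop_size), encode)
  }

  trace <- list()
  evaluate <- function(pop, gen) {
    ks <- vapply(pop, decode, integer(1))
    fit <- vapply(ks, fit_of, numeric(1))
    trace[[length(trace) + 1L]] <<-
      data.frame(generation = gen, k = ks, fitness = fit)
    fit
  }
  fit <- evaluate(pop, 0L)

  for (gen in seq_len(ga$n_generations)) {
    ord <- order(fit, vapply(pop, decode, integer(1)))
    elite <- pop[ord[seq_len(min(ga$elitism_count, length(pop)))]]
    tournament <- function() {
      pair <- sample.int(length(pop), 2L, replace = TRUE)
      pop[[pair[which.min(fit[pair])]]]
    }
    children <- list()
    while (length(children) < ga$pop_size - length(elite)) {
      p1 <- tournament(); p2 <- tournament()
      if (runif(1) < ga$crossover_prob && n_bits > 1L) {
        cut <- sample.int(n_bits - 1L, 1L)
        c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):n_bits])
        c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):n_bits])
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        flip <- runif(n_bits) < ga$mutation_prob
        child[flip] <- 1L - child[flip]
        if (length(children) < ga$pop_size - length(elite))
          children[[length(children) + 1L]] <- child
      }
    }
    pop <- c(elite, children)
    fit <- evaluate(pop, gen)
  }

  trace <- do.call(rbind, trace)
  evals <- if (!is.null(ctx)) collect_evaluations(ctx) else {
    ks <- sort(as.integer(ls(memo)))
    data.frame(k = ks, fitness = vapply(as.character(ks),
                                        function(key) memo[[key]],
                                        numeric(1)))
  }
  if (!any(is.finite(evals$fitness)))
    stop("no feasible k found by the genetic algorithm ",
         "(no fragmentation satisfies the usability constraint)")
  feas <- evals[is.finite(evals$fitness), ]
  best_row <- feas[order(feas$fitness, feas$k)[1L], ]
  out <- ga_result(best_row$k, best_row$fitness, trace, evals, "ga")
  if (!is.null(ctx)) out$model <- best_model_from(ctx, best_row$k)
  out
}
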