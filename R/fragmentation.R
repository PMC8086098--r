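#' Fragment a dataset into fully observed sub-datasets
#'
#' For each cluster of rows, keeps exactly the predictor columns that are
#' observed in *every* row of the cluster, which makes the resulting block
#' complete by construction while preserving row-disjointness across
#' sub-datasets (columns are dropped, never rows). A cluster is usable
#' only if its sample-to-predictor ratio `s / (q + 1) >= min_ratio`
#' (`q + 1` counts the intercept) and it retains at least one predictor;
#' other clusters are skipped with a recorded reason.
#'
#' @param data The training [tabular_dataset()].
#' @param clustering A [cluster_rows()] result covering all rows of `data`.
#' @param min_ratio Minimum usable sample-to-predictor ratio (default 2).
#' @param order Processing order of the kept sub-datasets:
#'   `"size_asc"` (default), `"size_desc"` or `"index"`; ties break on the
#'   smallest participating row index. In a posterior-to-prior chain the
#'   last fragment has the greatest influence on the final beliefs, so the
#'   default processes fragments in ascending size and ends the chain at
#'   the most data-rich fragment.
#' @return An object of class `fragmentation`: list with `subdatasets`
#'   (each a `sub_dataset` with `row_ids`, `predictor_subset`, `outcome`,
#'   `predictors`), `skipped` (data frame of rejected clusters and
#'   reasons), `n_total` and `schema`.
#' @examples
#' d <- tabular_dataset(1:4, matrix(c(1, 2, NA, NA, NA, NA, 3, 4), 4, 2))
#' cl <- cluster_rows(binarize_missingness(d), k = 2)
#' fragment(d, cl, min_ratio = 1)
#' @export
fragment <- function(data, clustering, min_ratio = 2, order = "size_asc") {
  if (n_rows(data) < 1L) stop("empty training data")
  if (length(clustering$labels) != n_rows(data))
    stop("clustering does not cover all rows of the data")
  order <- match.arg(order, c("size_asc", "size_desc", "index"))

  subs <- list()
  sk_cluster <- integer(); sk_rows <- integer(); sk_pred <- integer()
  sk_reason <- character()
  missing_by_col <- data$mask == 0L
  for (l in sort(unique(clustering$labels))) {
    rows <- which(clustering$labels == l)
    s <- length(rows)
    observed_all <- colSums(missing_by_col[rows, , drop = FALSE]) == 0L
    cols <- data$column_names[observed_all]
    q <- length(cols)
    if (q < 1L || s / (q + 1) < min_ratio) {
      sk_cluster <- c(sk_cluster, l); sk_rows <- c(sk_rows, s)
      sk_pred <- c(sk_pred, q)
      sk_reason <- c(sk_reason,
                     if (q < 1L) "no fully observed predictor"
                     else sprintf("sample/predictor ratio %.2f < %g",
                                  s / (q + 1), min_ratio))
      next
    }
    subs[[length(subs) + 1L]] <- structure(
      list(row_ids = rows, predictor_subset = cols,
           outcome = data$outcome[rows],
           predictors = data$predictors[rows, cols, drop = FALSE],
           cluster = l),
      class = "sub_dataset")
  }

  if (length(subs)) {
    s_sizes <- vapply(subs, function(x) length(x$row_ids), integer(1))
    first_row <- vapply(subs, function(x) min(x$row_ids), integer(1))
    ord <- switch(order,
                  size_desc = order(-s_sizes, first_row),
                  size_asc = order(s_sizes, first_row),
                  index = order(first_row))
    subs <- subs[ord]
  }
  skipped <- data.frame(cluster = sk_cluster, n_rows = sk_rows,
                        n_predictors = sk_pred, reason = sk_reason)

  # global observed-cell column means; dmu_fit() can centre every fragment
  # at these so all fragments estimate a common intercept
  col_center <- colMeans(data$predictors, na.rm = TRUE)
  col_center[!is.finite(col_center)] <- 0

  structure(list(subdatasets = subs, skipped = skipped,
                 n_total = n_rows(data), schema = data$column_names,
                 col_center = col_center),
            class = "fragmentation")
}

#' @export
print.fragmentation <- function(x, ...) {
  used <- sum(vapply(x$subdatasets, function(s) length(s$row_ids), integer(1)))
  cat(sprintf("<fragmentation> %d sub-datasets (%d/%d rows used, %d clusters skipped)\n",
              length(x$subdatasets), used, x$n_total, nrow(x$skipped)))
  for (s in utils::head(x$subdatasets, 10L))
    cat(sprintf("  s=%d q=%d  [%s]\n", length(s$row_ids),
                length(s$predictor_subset),
                paste(utils::head(s$predictor_subset, 8L), collapse = ", ")))
  if (length(x$subdatasets) > 10L) cat("  ...\n")
  invisible(x)
}

#' Check the structural guarantees of a fragmentation
#'
#' Asserts that every sub-dataset is fully observed and that row ids are
#' pairwise disjoint; a violation is an error naming the offending pair.
#'
#' @param frag A [fragment()] result.
#' @return List with `ok`, `n_subdatasets`, `rows_used`, `rows_discarded`.
#' @export
validate_fragmentation <- function(frag) {
  subs <- frag$subdatasets
  for (i in seq_along(subs))
    if (anyNA(subs[[i]]$predictors) || anyNA(subs[[i]]$outcome))
      stop("sub-dataset ", i, " contains missing values")
  if (length(subs) >= 2L) {
    for (l in seq_along(subs)) for (m in seq_along(subs)) {
      if (m <= l) next
      if (length(intersect(subs[[l]]$row_ids, subs[[m]]$row_ids)))
        stop(sprintf("sub-datasets %d and %d share rows", l, m))
    }
  }
  used <- sum(vapply(subs, function(s) length(s$row_ids), integer(1)))
  list(ok = TRUE, n_subdatasets = length(subs), rows_used = used,
       rows_discarded = frag$n_total - used)
}
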