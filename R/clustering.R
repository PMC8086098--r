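#' Binary transform of the missingness pattern
#'
#' Maps the predictor block to a 0/1 matrix: 0 where a cell is missing,
#' 1 where it is observed. Clustering operates on this matrix so that the
#' magnitude of observed values cannot influence the distances — only the
#' pattern of missingness does. The (always complete) outcome carries no
#' missingness information and is excluded.
#'
#' @param data A [tabular_dataset()].
#' @return Integer n x p matrix over \{0, 1\} with a `row_ids` attribute.
#' @export
binarize_missingness <- function(data) {
  structure(data$mask, row_ids = seq_len(n_rows(data)))
}

# Map user-facing metric names onto stats::dist() methods.
.metric_name <- function(metric) {
  switch(metric,
         euclidean = "euclidean",
         jaccard = "binary",
         stop("unsupported metric: ", metric))
}

#' Linkage tree of missingness patterns
#'
#' Agglomerative clustering of the rows of a binary missingness matrix.
#' Rows with identical patterns are collapsed to a single weighted point
#' before the tree is built (`hclust`'s `members` argument keeps the
#' agglomeration criteria exact for the supported linkages), which makes
#' the tree reusable and cheap even for thousands of rows; labels are
#' broadcast back to rows when the tree is cut.
#'
#' @param bin Binary matrix from [binarize_missingness()].
#' @param linkage One of `"complete"`, `"average"`, `"ward"`.
#' @param metric One of `"euclidean"`, `"jaccard"`.
#' @return An object of class `missingness_tree` holding the `hclust`
#'   merge tree, the unique patterns and the row-to-pattern map.
#' @export
missingness_linkage <- function(bin, linkage = "complete",
                                metric = "euclidean") {
  linkage <- match.arg(linkage, c("complete", "average", "ward"))
  method <- if (linkage == "ward") "ward.D2" else linkage
  key <- apply(bin, 1L, paste, collapse = "")
  ukey <- unique(key)                      # first-occurrence order
  pattern_of_row <- match(key, ukey)
  upat <- bin[match(ukey, key), , drop = FALSE]
  n_unique <- nrow(upat)
  hc <- NULL
  if (n_unique > 1L) {
    d <- dist(upat, method = .metric_name(metric))
    hc <- hclust(d, method = method,
                 members = as.vector(table(factor(pattern_of_row,
                                                  levels = seq_len(n_unique)))))
  }
  structure(list(hclust = hc, n_unique = n_unique,
                 pattern_of_row = pattern_of_row,
                 n = nrow(bin), linkage = linkage, metric = metric),
            class = "missingness_tree")
}

#' @export
print.missingness_tree <- function(x, ...) {
  cat(sprintf("<missingness_tree> %d rows, %d distinct patterns, %s linkage / %s\n",
              x$n, x$n_unique, x$linkage, x$metric))
  invisible(x)
}

#' Cut the missingness tree into k row clusters
#'
#' Cuts an agglomerative tree over the distinct missingness patterns at
#' `k` clusters and broadcasts the labels back to rows. Requests for more
#' clusters than there are distinct patterns assign each pattern its own
#' cluster (rows sharing a pattern are indistinguishable to the tree, and
#' for fragmentation purposes they observe the same columns).
#'
#' @param bin Binary matrix from [binarize_missingness()].
#' @param k Number of clusters, `1 <= k <= n`.
#' @param linkage,metric Passed to [missingness_linkage()] when no
#'   precomputed tree is supplied.
#' @param tree Optional precomputed [missingness_linkage()] result; saves
#'   rebuilding the tree when cutting at many values of `k`.
#' @return An object of class `row_clustering`: list with `k`, `labels`
#'   (length n, values in `1..k`) and `tree`.
#' @export
cluster_rows <- function(bin, k, linkage = "complete",
                         metric = "euclidean", tree = NULL) {
  n <- nrow(bin)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k cannot exceed the number of rows (", n, ")")
  if (is.null(tree)) tree <- missingness_linkage(bin, linkage, metric)
  labels_u <- if (k >= tree$n_unique || is.null(tree$hclust)) {
    seq_len(tree$n_unique)
  } else {
    cutree(tree$hclust, k = k)
  }
  structure(list(k = as.integer(k),
                 labels = as.integer(labels_u[tree$pattern_of_row]),
                 tree = tree),
            class = "row_clustering")
}

#' @export
print.row_clustering <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("<row_clustering> k=%d (%d non-empty), sizes: %s\n",
              x$k, length(sizes),
              paste(utils::head(sort(as.integer(sizes), decreasing = TRUE), 8L),
                    collapse = " ")))
  invisible(x)
}
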