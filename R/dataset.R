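#' Tabular dataset with a complete outcome and possibly missing predictors
#'
#' The central data container: a numeric outcome vector (no missing values
#' allowed — the method requires complete outcome data), an n x p predictor
#' matrix in which `NA` marks a missing cell, and the derived observation
#' mask (1 = observed, 0 = missing).
#'
#' @param outcome Numeric vector of length n with no missing values.
#' @param predictors Numeric n x p matrix (or data frame); `NA` = missing.
#' @param outcome_name Column name used when the table is written to disk.
#' @return An object of class `tabular_dataset`: a list with elements
#'   `outcome`, `predictors`, `mask` and `column_names`.
#' @examples
#' d <- tabular_dataset(c(1, 2), matrix(c(1, NA, 3, 4), 2, 2))
#' d$mask
#' @export
tabular_dataset <- function(outcome, predictors, outcome_name = "y") {
  outcome <- as.numeric(outcome)
  if (is.data.frame(predictors)) predictors <- as.matrix(predictors)
  storage.mode(predictors) <- "double"
  if (anyNA(outcome))
    stop("outcome must be fully observed (complete outcome data is required)")
  if (length(outcome) != nrow(predictors))
    stop("outcome length does not match predictor rows")
  if (nrow(predictors) < 1L || ncol(predictors) < 1L)
    stop("need at least one row and one predictor")
  if (is.null(colnames(predictors)))
    colnames(predictors) <- paste0("x", seq_len(ncol(predictors)))
  mask <- 1L - is.na(predictors) * 1L
  dimnames(mask) <- dimnames(predictors)
  structure(list(outcome = outcome,
                 predictors = predictors,
                 mask = mask,
                 column_names = colnames(predictors),
                 outcome_name = outcome_name),
            class = "tabular_dataset")
}

#' @export
print.tabular_dataset <- function(x, ...) {
  n <- length(x$outcome); p <- ncol(x$predictors)
  miss <- sum(x$mask == 0L)
  cat(sprintf("<tabular_dataset> %d rows, %d predictors, %.1f%% cells missing\n",
              n, p, 100 * miss / (n * p)))
  cat(sprintf("  complete rows: %d\n", sum(rowSums(x$mask == 0L) == 0L)))
  invisible(x)
}

#' Number of rows / predictors of a tabular dataset
#' @param data A `tabular_dataset`.
#' @return Integer count.
#' @export
n_rows <- function(data) length(data$outcome)

#' @rdname n_rows
#' @export
n_predictors <- function(data) ncol(data$predictors)

#' Indices of fully observed rows
#' @param data A `tabular_dataset`.
#' @return Integer vector of row indices with no missing predictor.
#' @export
complete_rows <- function(data) which(rowSums(data$mask == 0L) == 0L)

# subset rows (internal)
dataset_rows <- function(data, idx) {
  tabular_dataset(data$outcome[idx], data$predictors[idx, , drop = FALSE],
                  outcome_name = data$outcome_name)
}

#' Read a CSV table into a tabular dataset
#'
#' Cells matching one of `missing_codes` become missing predictor values.
#' Missing values in the outcome column are rejected: the modelling methods
#' in this package require a complete outcome.
#'
#' @param path CSV file with a header row.
#' @param outcome Name of the outcome column (default `"y"`).
#' @param missing_codes Character values treated as missing
#'   (default `""`, `"NA"`, `"NaN"`).
#' @return A [tabular_dataset()].
#' @export
read_table <- function(path, outcome = "y",
                       missing_codes = c("", "NA", "NaN")) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character())
  if (!outcome %in% names(raw))
    stop("outcome column '", outcome, "' not found in ", path)
  parse_col <- function(x, name) {
    x[x %in% missing_codes] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x))
    if (length(bad))
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1L], name, x[bad[1L]]))
    out
  }
  cols <- lapply(names(raw), function(nm) parse_col(raw[[nm]], nm))
  names(cols) <- names(raw)
  y <- cols[[outcome]]
  if (anyNA(y))
    stop("outcome column '", outcome,
         "' contains missing values; complete outcome data is required")
  pred <- do.call(cbind, cols[setdiff(names(cols), outcome)])
  tabular_dataset(y, pred, outcome_name = outcome)
}

#' Write a tabular dataset to CSV
#'
#' Missing predictor cells are written as empty fields, so a
#' [read_table()] round trip is lossless for values and mask.
#'
#' @param data A `tabular_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(data, path) {
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  df <- data.frame(fmt(data$outcome), apply(data$predictors, 2L, fmt),
                   check.names = FALSE)
  names(df) <- c(data$outcome_name, data$column_names)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
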