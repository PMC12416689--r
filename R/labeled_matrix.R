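# Container for a sample x feature expression matrix with binary labels.
# Samples are rows; labels are recoded to {0, 1} with the lexicographically
# smaller original label mapped to 0.

#' Construct a labeled sample-by-feature matrix
#'
#' The canonical container for a binary-classification expression dataset:
#' a numeric matrix with samples as rows and features as columns, plus a
#' binary label per sample.
#'
#' @param values Numeric matrix, `n_obs x n_features`.
#' @param labels Vector of length `n_obs` with exactly two distinct values;
#'   recoded to integers 0/1 (lexicographically smaller original value -> 0).
#' @param feature_ids Optional character vector of unique feature identifiers;
#'   defaults to column names or `"f1" ... "fD"`.
#' @param sample_ids Optional character vector of sample identifiers.
#' @return An object of class `labeled_matrix` with elements `values`
#'   (numeric matrix), `labels` (integer 0/1), `feature_ids`, `sample_ids`,
#'   and `label_levels` (the original two label values, in recode order).
#' @export
labeled_matrix <- function(values, labels, feature_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing value in matrix at row ", bad[1L], ", column ", bad[2L])
  }
  if (length(labels) != nrow(values)) {
    stop("labels length (", length(labels), ") != number of samples (",
         nrow(values), ")")
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) != 2L) {
    stop("not binary: found ", length(lv), " distinct label value(s)")
  }
  y <- as.integer(as.character(labels) == lv[2L])
  if (min(tabulate(y + 1L, 2L)) < 2L) {
    stop("each class needs at least 2 samples")
  }
  if (is.null(feature_ids)) {
    feature_ids <- colnames(values)
    if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(values)))
  }
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(values)) stop("feature_ids length mismatch")
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(values)) stop("sample_ids length mismatch")
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(values = values, labels = y, feature_ids = feature_ids,
         sample_ids = sample_ids, label_levels = lv),
    class = "labeled_matrix"
  )
}

#' @export
print.labeled_matrix <- function(x, ...) {
  cat("<labeled_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
      " features\n", sep = "")
  tab <- table(factor(x$labels, levels = 0:1))
  cat("  classes: ", x$label_levels[1L], "=0 (n=", tab[1L], "), ",
      x$label_levels[2L], "=1 (n=", tab[2L], ")\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_matrix <- function(x) dim(x$values)

#' Load a delimited matrix with binary labels
#'
#' Reads a CSV/TSV numeric matrix (samples as rows by default) and its binary
#' labels, either from a named column of the same file or from a one-column
#' companion file. Non-numeric cells and missing values are rejected with the
#' offending position; more than two label values is an error.
#'
#' @param path Path to the delimited matrix file. Delimiter is inferred from
#'   the extension (`.tsv`/`.txt` -> tab, otherwise comma) unless `sep` is
#'   given.
#' @param label_spec Either the name of the label column inside `path`, or the
#'   path of a companion file holding one label per sample.
#' @param transpose If `TRUE`, the file stores features as rows and is
#'   transposed after reading.
#' @param header Does the file carry a header row of feature identifiers?
#' @param sep Field separator; `NULL` to infer from the extension.
#' @return A [labeled_matrix()].
#' @export
load_labeled_matrix <- function(path, label_spec, transpose = FALSE,
                                header = TRUE, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  label_is_column <- is.character(label_spec) && length(label_spec) == 1L &&
    !file.exists(label_spec) && label_spec %in% names(df)
  if (label_is_column) {
    labels <- df[[label_spec]]
    df <- df[setdiff(names(df), label_spec)]
  } else if (file.exists(label_spec)) {
    labels <- utils::read.table(label_spec, header = FALSE,
                                stringsAsFactors = FALSE)[[1L]]
  } else {
    stop("label_spec '", label_spec,
         "' is neither a column of the matrix file nor an existing file")
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stop("non-numeric cell at row ", bad[1L], ", column ", names(df)[j])
      }
      df[[j]] <- num
    }
  }
  values <- as.matrix(df)
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("missing value at row ", bad[1L], ", column ", bad[2L])
  }
  if (transpose) {
    values <- t(values)
    dimnames(values) <- list(NULL, rownames(df))
  }
  nlab <- length(unique(as.character(labels)))
  if (nlab != 2L) stop("not binary: found ", nlab, " label values")
  labeled_matrix(values, labels)
}

#' Write a labeled matrix to a delimited file
#'
#' Inverse of [load_labeled_matrix()]: writes the sample-by-feature matrix
#' with a trailing `label` column holding the original label values, using
#' full double precision so a round trip is bit-exact.
#'
#' @param data A [labeled_matrix()].
#' @param path Output path (`.tsv`/`.txt` -> tab separated, else comma).
#' @return `path`, invisibly.
#' @export
write_labeled_matrix <- function(data, path) {
  stopifnot(inherits(data, "labeled_matrix"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(data$values, check.names = FALSE)
  df$label <- data$label_levels[data$labels + 1L]
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
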