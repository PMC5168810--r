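#' Two-condition expression dataset
#'
#' Container for a feature-by-sample expression matrix with binary condition
#' labels. Counts are expected by the count-based statistics
#' ([compute_voom_t()], [compute_nb_wald()]); the generic statistics
#' ([compute_sam_t()], [compute_sam_ranksum()], [compute_moderated_t()])
#' accept any real-valued matrix.
#'
#' All downstream statistics are oriented as group 2 minus group 1, where
#' group 2 is the second level of \code{labels} (alphabetical if \code{labels}
#' is a plain vector). A positive statistic therefore means higher expression
#' in group 2.
#'
#' @param values numeric matrix, M features x N samples, no missing values.
#' @param feature_ids character vector of M unique feature identifiers.
#'   Defaults to rownames of \code{values}.
#' @param sample_ids character vector of N sample identifiers. Defaults to
#'   colnames of \code{values}.
#' @param labels vector of length N with exactly two distinct values (factor,
#'   character or numeric); both groups must be non-empty.
#' @return An object of class \code{"expression_dataset"}: a list with
#'   elements \code{values}, \code{feature_ids}, \code{sample_ids},
#'   \code{labels} (two-level factor).
#' @export
expression_dataset <- function(values, feature_ids = rownames(values),
                               sample_ids = colnames(values), labels) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  M <- nrow(values)
  N <- ncol(values)
  if (M < 1L) stop("need at least one feature")
  if (N < 4L) stop("need at least 4 samples (2 per group)")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at feature %d, sample %d", idx[1L], idx[2L]))
  }
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(M))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(N))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != M) stop("feature_ids length mismatch")
  if (length(sample_ids) != N) stop("sample_ids length mismatch")
  if (anyDuplicated(feature_ids))
    stop("duplicate feature_ids: ", paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  labels <- as.factor(labels)
  labels <- droplevels(labels)
  if (length(labels) != N) stop("labels length must equal number of samples")
  if (nlevels(labels) != 2L) stop("labels must have exactly two distinct values")
  if (any(table(labels) < 1L)) stop("both label groups must be non-empty")
  dimnames(values) <- list(feature_ids, sample_ids)
  structure(list(values = values, feature_ids = feature_ids,
                 sample_ids = sample_ids, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$labels)
  cat(sprintf("groups: %s (n=%d, group 1) vs %s (n=%d, group 2)\n",
              names(tab)[1L], tab[1L], names(tab)[2L], tab[2L]))
  invisible(x)
}

# logical mask of group-2 samples (second factor level)
group2_mask <- function(labels) as.integer(labels) == 2L

#' Read an expression matrix from TSV/CSV
#'
#' Column 1 holds feature identifiers, the header row holds sample
#' identifiers. The delimiter is chosen from the file extension
#' (\code{.csv} means comma, anything else tab).
#'
#' @param path path to the matrix file.
#' @return list with \code{values} (numeric matrix), \code{feature_ids},
#'   \code{sample_ids}; combine with labels via [expression_dataset()].
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("matrix file needs a feature-id column plus data columns")
  feature_ids <- df[[1L]]
  if (anyDuplicated(feature_ids))
    stop("duplicate feature IDs in ", path, ": ",
         paste(utils::head(unique(feature_ids[duplicated(feature_ids)]), 5L), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(values) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at feature '%s', sample '%s'",
                 feature_ids[bad[1L, 1L]], colnames(raw)[bad[1L, 2L]]))
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at feature '%s', sample '%s'",
                 feature_ids[idx[1L]], colnames(raw)[idx[2L]]))
  }
  dimnames(values) <- list(feature_ids, colnames(raw))
  list(values = values, feature_ids = feature_ids, sample_ids = colnames(raw))
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_matrix()]: feature IDs in column 1, sample IDs as header.
#'
#' @param values numeric matrix with rownames/colnames.
#' @param path output path.
#' @export
write_matrix <- function(values, path) {
  df <- data.frame(feature_id = rownames(values), values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read condition labels from a two-column TSV
#'
#' Expects columns \code{sample_id} and \code{condition} (header optional
#' when the first row parses as data for known sample ids).
#'
#' @param path path to the label file.
#' @param sample_ids optional character vector; labels are reordered to match
#'   and checked for completeness.
#' @return factor of condition labels.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("label file needs sample_id and condition columns")
  lab <- df[[2L]]
  names(lab) <- df[[1L]]
  if (!is.null(sample_ids)) {
    miss <- setdiff(sample_ids, names(lab))
    if (length(miss) > 0L)
      stop("labels missing for samples: ", paste(miss, collapse = ", "))
    lab <- lab[sample_ids]
  }
  factor(unname(lab))
}

#' Scale and round continuous values to integers
#'
#' Multiplies by \code{factor} and rounds half away from zero. Used to feed
#' continuous measurements (e.g. methylation proportions) into count-only
#' statistics.
#'
#' @param values numeric matrix or vector.
#' @param factor positive scale factor (e.g. 1000).
#' @return matrix (or vector) of integers, same shape as \code{values}.
#' @export
scale_round <- function(values, factor = 1000) {
  if (factor <= 0) stop("factor must be positive")
  x <- values * factor
  # round half away from zero (base round() rounds half to even)
  out <- sign(x) * floor(abs(x) + 0.5)
  out
}
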