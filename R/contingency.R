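# Contingency tables: the common currency of the association layer.

#' Construct a contingency table
#'
#' An r x c table of nonnegative integer counts with labelled rows and
#' columns; all association statistics in the package consume this type.
#'
#' @param counts matrix (or coercible) of nonnegative integers, at least 2x2.
#' @param row_labels,col_labels optional character vectors of dimension
#'   labels; taken from `dimnames(counts)` when absent.
#' @return a `contingency_table` (an integer matrix with class attribute).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  m <- as.matrix(counts)
  fail_if(any(is.na(m)), "counts must not contain NA")
  fail_if(any(m < 0), "counts must be nonnegative")
  fail_if(any(m != round(m)), "counts must be integers")
  fail_if(nrow(m) < 2 || ncol(m) < 2, "table must be at least 2x2")
  fail_if(sum(m) <= 0, "grand total must be positive")
  storage.mode(m) <- "integer"
  rownames(m) <- row_labels %||% rownames(m) %||% paste0("r", seq_len(nrow(m)))
  colnames(m) <- col_labels %||% colnames(m) %||% paste0("c", seq_len(ncol(m)))
  structure(m, class = c("contingency_table", "matrix", "array"))
}

as_contingency <- function(x) {
  if (inherits(x, "contingency_table")) x else contingency_table(x)
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("contingency_table %dx%d (N = %d)\n", nrow(x), ncol(x), sum(x)))
  print(unclass(x))
  invisible(x)
}
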