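# Cohort data model and CSV input/output.
#
# A cohort is one row per patient: clinical covariates, the four
# marker-by-compartment TIL densities (cells/mm^2), and the binary pCR
# outcome. Invasive-margin densities may be missing, and are missing jointly
# (a section without an evaluable invasive margin yields neither CD3-IM nor
# CD8-IM).

.subtype_levels  <- c("TNBC", "luminal", "HER2")
.size_levels     <- c("T1", "T2", "T3_4")
.nodal_levels    <- c("negative", "positive", "unknown")
.stage_levels    <- c("I", "IIA", "IIB", "III")
.meno_levels     <- c("pre", "post")
.density_cols    <- c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im")
.cohort_cols <- c("patient_id", "subtype", "tumor_size", "nodal_status",
                  "stage_group", "er_positive", "pr_positive", "her2_positive",
                  "ki67_percent", "menopausal", .density_cols, "pcr")

#' Construct and validate a cohort table
#'
#' Coerces a data frame with the canonical columns into a `cohort_table`,
#' enforcing the invariants of the data model: unique patient identifiers,
#' nonnegative densities, jointly-missing invasive-margin markers, and Ki-67
#' within \[0, 100\] when present.
#'
#' @param df data frame with columns `patient_id`, `subtype` (TNBC/luminal/
#'   HER2), `tumor_size` (T1/T2/T3_4), `nodal_status`, `stage_group`,
#'   `er_positive`, `pr_positive`, `her2_positive` (logical), `ki67_percent`,
#'   `menopausal` (pre/post), `cd3_ct`, `cd8_ct`, `cd3_im`, `cd8_im`
#'   (cells/mm^2), and `pcr` (logical).
#' @param provenance one of `"user"`, `"synthetic"`, `"fixture"`.
#' @return a `cohort_table` (a validated data frame).
#' @export
cohort_table <- function(df, provenance = "user") {
  missing_cols <- setdiff(.cohort_cols, names(df))
  fail_if(length(missing_cols) > 0,
          "missing required column(s): %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df)[, .cohort_cols]
  df$patient_id <- as.character(df$patient_id)
  df$subtype      <- factor(as.character(df$subtype), levels = .subtype_levels)
  df$tumor_size   <- factor(as.character(df$tumor_size), levels = .size_levels)
  df$nodal_status <- factor(as.character(df$nodal_status), levels = .nodal_levels)
  df$stage_group  <- factor(as.character(df$stage_group), levels = .stage_levels)
  df$menopausal   <- factor(as.character(df$menopausal), levels = .meno_levels)
  for (col in c("er_positive", "pr_positive", "her2_positive", "pcr")) {
    df[[col]] <- as.logical(df[[col]])
  }
  for (col in c("ki67_percent", .density_cols)) {
    df[[col]] <- as.numeric(df[[col]])
  }
  validate_cohort(df)
  structure(df, class = c("cohort_table", "data.frame"),
            provenance = provenance)
}

#' @rdname cohort_table
#' @param df data frame to check.
#' @return invisibly `TRUE`; stops with a row-numbered message on violation.
#' @export
validate_cohort <- function(df) {
  bad_rows <- function(cond) which(!is.na(cond) & cond)
  dup <- df$patient_id[duplicated(df$patient_id)]
  fail_if(length(dup) > 0, "duplicate patient_id: %s",
          paste(unique(dup), collapse = ", "))
  for (col in .density_cols) {
    neg <- bad_rows(df[[col]] < 0)
    fail_if(length(neg) > 0, "negative density in column %s, row(s) %s",
            col, paste(neg, collapse = ", "))
  }
  im_mismatch <- which(is.na(df$cd3_im) != is.na(df$cd8_im))
  fail_if(length(im_mismatch) > 0,
          "cd3_im and cd8_im must be missing jointly; row(s) %s",
          paste(im_mismatch, collapse = ", "))
  ki_bad <- bad_rows(df$ki67_percent < 0 | df$ki67_percent > 100)
  fail_if(length(ki_bad) > 0, "ki67_percent outside [0, 100] in row(s) %s",
          paste(ki_bad, collapse = ", "))
  ct_na <- which(is.na(df$cd3_ct) | is.na(df$cd8_ct))
  fail_if(length(ct_na) > 0,
          "center-of-tumor densities are required; missing in row(s) %s",
          paste(ct_na, collapse = ", "))
  invisible(TRUE)
}

#' Read a patient cohort from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header row) with one row per patient. Blank
#' density cells become missing values; invasive-margin markers must then be
#' blank jointly. Column names may be remapped through `schema`.
#'
#' @param source path or connection to a CSV file.
#' @param schema optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(cd3_ct = "CD3.CT.density")`.
#' @param provenance provenance tag stored on the result.
#' @return a [cohort_table()]. A header-only file yields an empty cohort.
#' @export
read_cohort <- function(source, schema = NULL, provenance = "user") {
  raw <- utils::read.csv(source, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      fail_if(!schema[[canonical]] %in% names(raw),
              "schema maps %s to %s, which is not a column of the file",
              canonical, schema[[canonical]])
      names(raw)[names(raw) == schema[[canonical]]] <- canonical
    }
  }
  missing_cols <- setdiff(.cohort_cols, names(raw))
  fail_if(length(missing_cols) > 0,
          "missing required column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(raw) == 0) {
    empty <- raw[, .cohort_cols]
    return(cohort_table(empty, provenance = provenance))
  }
  cohort_table(raw, provenance = provenance)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: missing values are emitted as empty cells, so
#' a read/write round trip preserves every field including invasive-margin
#' missingness.
#'
#' @param cohort a [cohort_table()].
#' @param sink file path or connection.
#' @return number of data rows written, invisibly.
#' @export
write_cohort <- function(cohort, sink) {
  utils::write.csv(as.data.frame(cohort), sink, row.names = FALSE, na = "")
  invisible(nrow(cohort))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d patients (provenance: %s)\n",
              nrow(x), attr(x, "provenance") %||% "user"))
  if (nrow(x) > 0) {
    cat(sprintf("  subtypes: %s\n",
                paste(sprintf("%s=%d", levels(x$subtype),
                              tabulate(x$subtype, 3)), collapse = " ")))
    cat(sprintf("  IM densities present: %d of %d; pCR: %d (%d%%)\n",
                sum(!is.na(x$cd3_im)), nrow(x), sum(x$pcr, na.rm = TRUE),
                round_half_up(100 * mean(x$pcr, na.rm = TRUE))))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rows of `cohort` with evaluable invasive-margin densities.
im_present <- function(cohort) cohort[!is.na(cohort$cd3_im), , drop = FALSE]
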