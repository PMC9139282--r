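# ROC curves, AUC, and Youden-index cut-off selection.
#
# Test polarity: higher density predicts the positive class (pCR). A patient
# is called positive at threshold t iff value > t (strictly). This strict
# convention matches the printed cut-off/high-group pairing of the reference
# cohort, where the cut-off 1186.80 cells/mm^2 defines a high group of
# >= 1186.81 cells/mm^2.

#' Empirical ROC curve
#'
#' Builds the ROC curve of a continuous marker against a binary outcome.
#' Candidate thresholds are the unique observed values plus -Inf/+Inf
#' sentinels; the curve therefore starts at (0, 0) (threshold +Inf, nobody
#' called positive) and ends at (1, 1).
#'
#' @param values numeric marker values (e.g. cells/mm^2); pairs with missing
#'   values are dropped.
#' @param labels logical outcome (TRUE = positive class); both classes must
#'   be present after dropping missing pairs.
#' @return an `iscr_roc` data frame with columns `threshold`, `sensitivity`,
#'   `fpr` (1 - specificity), ordered strictest to most permissive, with
#'   attributes `n_pos`, `n_neg`.
#' @export
roc_curve <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]
  labels <- as.logical(labels[keep])
  fail_if(any(!is.finite(values)), "values must be finite")
  fail_if(!any(labels) || all(labels),
          "both outcome classes must be present to build an ROC curve")
  thr <- c(Inf, sort(unique(values), decreasing = TRUE), -Inf)
  pos <- values[labels]
  neg <- values[!labels]
  sens <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  structure(data.frame(threshold = thr, sensitivity = sens, fpr = fpr),
            class = c("iscr_roc", "data.frame"),
            n_pos = length(pos), n_neg = length(neg))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under an [roc_curve()]. With thresholds at every
#' observed value, this equals the Mann-Whitney pair-counting statistic
#' (concordant pairs + half ties) / (n_pos * n_neg).
#'
#' @param curve an `iscr_roc`.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "iscr_roc"))
  x <- curve$fpr
  y <- curve$sensitivity
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

#' Youden-index optimal cut-off
#'
#' Chooses the threshold maximizing J = sensitivity + specificity - 1 over
#' the observed marker values (positive call iff value > threshold). Ties on
#' J are broken toward higher sensitivity, then toward the lower threshold.
#' When the marker is anti-discriminant (AUC < 0.5) a polarity warning flag
#' is set rather than silently flipping the direction.
#'
#' @inheritParams roc_curve
#' @return a `youden_cutoff` list: `threshold` (an observed value),
#'   `sensitivity`, `specificity`, `j`, `auc`, `n_used`, `n_pos`, `n_neg`,
#'   `polarity_warning`.
#' @examples
#' youden_cutoff(c(1, 2, 3, 4, 5), c(FALSE, FALSE, TRUE, FALSE, TRUE))
#' @export
youden_cutoff <- function(values, labels) {
  keep <- !is.na(values) & !is.na(labels)
  curve <- roc_curve(values[keep], labels[keep])
  obs <- is.finite(curve$threshold)
  cand <- curve[obs, , drop = FALSE]
  j <- cand$sensitivity - cand$fpr
  best_j <- max(j)
  at <- which(j == best_j)
  if (length(at) > 1) {               # higher sensitivity first ...
    at <- at[cand$sensitivity[at] == max(cand$sensitivity[at])]
    at <- at[which.min(cand$threshold[at])]  # ... then lower threshold
  }
  a <- auc(curve)
  structure(list(threshold = cand$threshold[at],
                 sensitivity = cand$sensitivity[at],
                 specificity = 1 - cand$fpr[at],
                 j = best_j,
                 auc = a,
                 n_used = sum(keep),
                 n_pos = attr(curve, "n_pos"),
                 n_neg = attr(curve, "n_neg"),
                 polarity_warning = a < 0.5),
            class = "youden_cutoff")
}

#' @export
print.youden_cutoff <- function(x, ...) {
  cat(sprintf(
    "Youden cut-off %.2f (J = %.3f): sensitivity %.1f%%, specificity %.1f%%, AUC %.3f (n = %d)%s\n",
    x$threshold, x$j, 100 * x$sensitivity, 100 * x$specificity, x$auc,
    x$n_used, if (x$polarity_warning) " [polarity warning: AUC < 0.5]" else ""))
  invisible(x)
}

.marker_keys <- c("cd3_ct", "cd8_ct", "cd3_im", "cd8_im")

#' Derive the per-marker cut-off set for a cohort
#'
#' Runs [youden_cutoff()] for each marker x compartment against pCR. CT
#' cut-offs use every patient; IM cut-offs use only patients with an
#' evaluable invasive margin (pairwise deletion), matching the two
#' denominators the analysis tracks throughout.
#'
#' @param cohort a [cohort_table()] with both pCR classes present.
#' @return a `cutoff_set` data frame: one row per key (`cd3_ct`, `cd8_ct`,
#'   `cd3_im`, `cd8_im`) with `threshold`, `sensitivity`, `specificity`,
#'   `auc`, `n_used`, `polarity_warning`.
#' @export
derive_cutoffs <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  fail_if(nrow(cohort) < 2, "cannot derive cut-offs from fewer than 2 patients")
  rows <- lapply(.marker_keys, function(key) {
    yc <- youden_cutoff(cohort[[key]], cohort$pcr)
    data.frame(key = key, threshold = yc$threshold,
               sensitivity = yc$sensitivity, specificity = yc$specificity,
               auc = yc$auc, n_used = yc$n_used,
               polarity_warning = yc$polarity_warning)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("cutoff_set", "data.frame"))
}

#' Serialize / deserialize a cut-off set
#'
#' @param cutoffs a `cutoff_set`.
#' @param path JSON file path.
#' @return `read_cutoffs` returns a `cutoff_set`.
#' @export
write_cutoffs <- function(cutoffs, path) {
  jsonlite::write_json(as.data.frame(cutoffs), path, digits = NA,
                       auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_cutoffs
#' @export
read_cutoffs <- function(path) {
  df <- jsonlite::fromJSON(path)
  fail_if(!all(.marker_keys %in% df$key),
          "cut-off file must define all four marker keys")
  structure(df, class = c("cutoff_set", "data.frame"))
}

#' Dichotomize a cohort against a cut-off set
#'
#' Flags each marker x compartment density as `"high"` (strictly greater
#' than the threshold) or `"low"`; missing IM densities yield missing IM
#' flags, while CT flags are always defined.
#'
#' @param cohort a [cohort_table()].
#' @param cutoffs a `cutoff_set` from [derive_cutoffs()] or [read_cutoffs()],
#'   defining thresholds for all four keys.
#' @return a `highlow_profile` data frame: `patient_id` plus character
#'   columns `cd3_ct`, `cd8_ct`, `cd3_im`, `cd8_im` in {"high", "low", NA}.
#' @export
apply_cutoffs <- function(cohort, cutoffs) {
  stopifnot(inherits(cohort, "cohort_table"))
  fail_if(!all(.marker_keys %in% cutoffs$key),
          "cutoffs must define all four marker keys")
  out <- data.frame(patient_id = cohort$patient_id,
                    stringsAsFactors = FALSE)
  for (key in .marker_keys) {
    thr <- cutoffs$threshold[cutoffs$key == key][1]
    out[[key]] <- ifelse(is.na(cohort[[key]]), NA_character_,
                         ifelse(cohort[[key]] > thr, "high", "low"))
  }
  structure(out, class = c("highlow_profile", "data.frame"))
}
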