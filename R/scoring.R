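# ISCR scoring: combine the four high/low flags into the 0-4 score, the
# CT-only biopsy variant (0-2), the three-tier grouping and the binary
# grouping used in the logistic model.
#
# The score is the count of "high" flags among CD3-CT, CD8-CT, CD3-IM,
# CD8-IM: 4 = both markers high in both compartments, 0 = both low in both,
# intermediate values count the elevated marker-compartment pairs. Patients
# without evaluable IM flags have no full score and propagate missingness
# through tier and binary group.

#' Full ISCR score (0-4)
#'
#' @param profile a `highlow_profile` from [apply_cutoffs()], or a data
#'   frame with character columns `cd3_ct`, `cd8_ct`, `cd3_im`, `cd8_im`
#'   in {"high", "low", NA}.
#' @return integer vector 0-4, `NA` where any IM flag is missing.
#' @export
full_iscr <- function(profile) {
  flags <- as.matrix(profile[, .marker_keys, drop = FALSE])
  bad <- flags[!is.na(flags) & !flags %in% c("high", "low")]
  fail_if(length(bad) > 0, "invalid flag value(s): %s",
          paste(unique(bad), collapse = ", "))
  ct_na <- is.na(flags[, "cd3_ct"]) | is.na(flags[, "cd8_ct"])
  fail_if(any(ct_na), "CT flags must never be missing")
  score <- rowSums(flags == "high")
  score[is.na(flags[, "cd3_im"]) | is.na(flags[, "cd8_im"])] <- NA
  as.integer(score)
}

#' Biopsy ISCR score (0-2, CT only)
#'
#' The biopsy variant usable when no invasive margin is sampled: 2 (High)
#' when both CT markers are high, 1 (Intermediate) when exactly one is, 0
#' (Low) when both are low.
#'
#' @param cd3_ct_flag,cd8_ct_flag character vectors in {"high", "low"}; a
#'   `highlow_profile` may be passed as the first argument instead.
#' @return integer vector 0-2.
#' @export
biopsy_iscr <- function(cd3_ct_flag, cd8_ct_flag = NULL) {
  if (is.data.frame(cd3_ct_flag)) {
    cd8_ct_flag <- cd3_ct_flag$cd8_ct
    cd3_ct_flag <- cd3_ct_flag$cd3_ct
  }
  fail_if(any(is.na(cd3_ct_flag)) || any(is.na(cd8_ct_flag)),
          "CT flags must not be missing")
  fail_if(!all(c(cd3_ct_flag, cd8_ct_flag) %in% c("high", "low")),
          "flags must be \"high\" or \"low\"")
  as.integer((cd3_ct_flag == "high") + (cd8_ct_flag == "high"))
}

#' Three-tier ISCR grouping
#'
#' Scores 0-1 are Low, 2 is Intermediate, 3-4 are High.
#'
#' @param score integer vector of full ISCR scores (0-4); `NA` propagates.
#' @return factor with levels Low, Intermediate, High.
#' @export
iscr_tier <- function(score) {
  fail_if(any(!is.na(score) & !score %in% 0:4), "score must be in 0..4")
  out <- rep(NA_character_, length(score))
  out[!is.na(score) & score <= 1] <- "Low"
  out[!is.na(score) & score == 2] <- "Intermediate"
  out[!is.na(score) & score >= 3] <- "High"
  factor(out, levels = c("Low", "Intermediate", "High"))
}

#' Binary ISCR grouping (0-2 vs 3-4)
#'
#' The dichotomy used in the logistic model: scores 0, 1, 2 against 3, 4.
#'
#' @inheritParams iscr_tier
#' @return factor with levels `low012`, `high34`; `NA` propagates.
#' @export
binary_group <- function(score) {
  fail_if(any(!is.na(score) & !score %in% 0:4), "score must be in 0..4")
  factor(ifelse(is.na(score), NA_character_,
                ifelse(score >= 3, "high34", "low012")),
         levels = c("low012", "high34"))
}

#' Score a whole cohort
#'
#' Convenience wrapper: applies a cut-off set, computes the full and biopsy
#' ISCR, tier and binary grouping, and returns the cohort with the score
#' columns appended.
#'
#' @param cohort a [cohort_table()].
#' @param cutoffs a `cutoff_set`; derived from the cohort itself when
#'   omitted.
#' @return the cohort data frame with added columns `iscr`, `iscr_biopsy`,
#'   `iscr_tier`, `iscr_binary`.
#' @export
score_cohort <- function(cohort, cutoffs = NULL) {
  if (is.null(cutoffs)) cutoffs <- derive_cutoffs(cohort)
  profile <- apply_cutoffs(cohort, cutoffs)
  out <- as.data.frame(cohort)
  out$iscr <- full_iscr(profile)
  out$iscr_biopsy <- biopsy_iscr(profile)
  out$iscr_tier <- iscr_tier(out$iscr)
  out$iscr_binary <- binary_group(out$iscr)
  out
}
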