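# Packaged reference tables.

#' Reference contingency tables from the original cohort
#'
#' Returns the printed contingency tables and marginal counts of the
#' 103-patient neoadjuvant breast-cancer cohort on which the ISCR scoring
#' scheme was evaluated. Per-patient raw data were never deposited; these
#' aggregate tables are what the published association analysis reduces to,
#' and every reproducible published statistic in this package is recomputed
#' from them.
#'
#' Tables involving the invasive margin or the ISCR are restricted to the 75
#' patients with an evaluable invasive margin; the remaining 28 patients
#' lack both IM densities.
#'
#' @return a list with elements:
#' \describe{
#'   \item{tables}{named list of [contingency_table()] objects
#'     (`subtype_pcr`, `iscr_tier_pcr`, `cd3_ct_pcr`, `cd8_ct_pcr`,
#'     `cd3_im_pcr`, `cd8_im_pcr`, `her2_pcr`, `tumor_size_pcr`,
#'     `nodal_pcr`, `stage_pcr`, `er_pcr`, `pr_pcr`, `ki67_pcr`,
#'     `subtype_im_split`).}
#'   \item{counts}{named list of labelled count vectors
#'     (`iscr_distribution` over scores 0--4; `subtype_total`).}
#' }
#' @examples
#' fx <- reference_tables()
#' fx$tables$iscr_tier_pcr
#' sum(fx$counts$iscr_distribution)  # 75 patients with an evaluable IM
#' @export
reference_tables <- function() {
  path <- system.file("extdata", "reference_tables.json", package = "iscr",
                      mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tables <- lapply(raw$tables, function(tb) {
    contingency_table(tb$counts, row_labels = tb$rows, col_labels = tb$cols)
  })
  counts <- lapply(raw$counts, function(cv) {
    stats::setNames(as.integer(cv$counts), cv$labels)
  })
  list(tables = tables, counts = counts)
}
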