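# End-to-end orchestration: cohort in -> cut-offs -> ISCR -> association
# tables and predictive values out, mirroring the layout of the published
# summary, cut-off, distribution, association, logistic, and
# predictive-value tables. Two denominators are tracked explicitly
# throughout: all patients, and the IM-present subset to which every
# IM-dependent analysis is restricted.

#' Run the full ISCR analysis pipeline
#'
#' Deterministic function of (cohort, config): derives Youden cut-offs,
#' scores every patient, and assembles the report bundle. IM-dependent
#' analyses are restricted to patients with an evaluable invasive margin;
#' when no patient has one, the IM and ISCR tables are omitted with a
#' notice.
#'
#' @param cohort a [cohort_table()] with both pCR classes present.
#' @param config optional list: `cutoffs` (a pre-derived `cutoff_set`;
#'   derived in-sample when absent), `conf` (CI level, default 0.95).
#' @return an `iscr_report` list:
#' \describe{
#'   \item{summary_table}{median and range per marker x compartment.}
#'   \item{cutoff_table}{the `cutoff_set` used.}
#'   \item{distribution_table}{ISCR 0-4 counts and percents (IM-present).}
#'   \item{association_tables}{per covariate: counts x pCR, per-group
#'     percents, Fisher exact p.}
#'   \item{logistic_table}{univariate logistic fits (binary and ordinal
#'     ISCR).}
#'   \item{predictive_table}{PPV/NPV per marker flag and for ISCR 0-1 vs
#'     2-4.}
#'   \item{scored}{the scored cohort.}
#'   \item{metadata}{denominators, provenance, config echo.}
#' }
#' @export
run_pipeline <- function(cohort, config = list()) {
  stopifnot(inherits(cohort, "cohort_table"))
  fail_if(nrow(cohort) < 2, "cannot analyse a cohort of fewer than 2 patients")
  fail_if(length(unique(cohort$pcr)) < 2,
          "both pCR classes must be present in the cohort")
  conf <- config$conf %||% 0.95
  cutoffs <- config$cutoffs %||% derive_cutoffs(cohort)
  scored <- score_cohort(cohort, cutoffs)
  imp <- scored[!is.na(scored$cd3_im), , drop = FALSE]
  has_im <- nrow(imp) > 0
  if (!has_im) {
    message("no patient has evaluable IM densities: IM and ISCR tables omitted")
  }

  summary_table <- do.call(rbind, lapply(.marker_keys, function(k) {
    v <- cohort[[k]][!is.na(cohort[[k]])]
    data.frame(key = k, n = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               min = if (length(v)) min(v) else NA_real_,
               max = if (length(v)) max(v) else NA_real_)
  }))

  distribution_table <- if (has_im) {
    counts <- tabulate(scored$iscr + 1L, 5L)
    data.frame(score = 0:4, count = counts,
               percent = round_half_up(100 * counts / sum(counts)))
  }

  flag_profile <- apply_cutoffs(cohort, cutoffs)
  assoc_input <- list(
    subtype = scored$subtype,
    tumor_size = scored$tumor_size,
    nodal_status = factor(replace(as.character(scored$nodal_status),
                                  scored$nodal_status == "unknown", NA)),
    stage_group = scored$stage_group,
    er = factor(ifelse(scored$er_positive, "positive", "negative")),
    pr = factor(ifelse(scored$pr_positive, "positive", "negative")),
    her2 = factor(ifelse(scored$her2_positive, "positive", "negative")),
    ki67 = factor(ifelse(is.na(scored$ki67_percent), NA,
                         ifelse(scored$ki67_percent >= 40, "ge40",
                                ifelse(scored$ki67_percent >= 15, "15_39",
                                       "lt15"))),
                  levels = c("ge40", "15_39", "lt15")),
    cd3_ct_flag = factor(flag_profile$cd3_ct, levels = c("high", "low")),
    cd8_ct_flag = factor(flag_profile$cd8_ct, levels = c("high", "low")))
  if (has_im) {
    assoc_input$cd3_im_flag <- factor(flag_profile$cd3_im,
                                      levels = c("high", "low"))
    assoc_input$cd8_im_flag <- factor(flag_profile$cd8_im,
                                      levels = c("high", "low"))
    assoc_input$iscr_tier <- scored$iscr_tier
  }
  association_tables <- lapply(assoc_input, function(g) {
    keep <- !is.na(g) & !is.na(scored$pcr)
    g <- droplevels(factor(g[keep]))
    y <- scored$pcr[keep]
    if (nlevels(g) < 2 || length(unique(y)) < 2) return(NULL)
    counts <- contingency_table(
      cbind(pCR = tapply(y, g, sum), no_pCR = tapply(!y, g, sum)))
    list(counts = counts,
         proportions = proportions_from_table(counts),
         fisher_p = fisher_exact(counts)$p_value,
         n = sum(keep))
  })
  association_tables <- Filter(Negate(is.null), association_tables)

  logistic_table <- if (has_im && length(unique(imp$pcr)) == 2 &&
                          nlevels(droplevels(imp$iscr_binary)) == 2) {
    list(iscr_binary = logistic_univariate(imp$iscr_binary, imp$pcr),
         iscr_ordinal = logistic_univariate(imp$iscr, imp$pcr))
  }

  pv_for <- function(high_flag, y) {
    tab <- contingency_table(rbind(
      high = c(pCR = sum(y[high_flag]), no_pCR = sum(!y[high_flag])),
      low = c(pCR = sum(y[!high_flag]), no_pCR = sum(!y[!high_flag]))))
    predictive_values(tab, conf = conf)
  }
  predictive_table <- if (has_im) {
    flags_imp <- apply_cutoffs(
      cohort_table(as.data.frame(imp)[, .cohort_cols],
                   provenance = attr(cohort, "provenance") %||% "user"),
      cutoffs)
    out <- lapply(.marker_keys, function(k) {
      tryCatch(pv_for(flags_imp[[k]] == "high", imp$pcr),
               error = function(e) NULL)
    })
    names(out) <- .marker_keys
    out$iscr_2plus <- tryCatch(pv_for(imp$iscr >= 2, imp$pcr),
                               error = function(e) NULL)
    Filter(Negate(is.null), out)
  }

  structure(list(summary_table = summary_table,
                 cutoff_table = cutoffs,
                 distribution_table = distribution_table,
                 association_tables = association_tables,
                 logistic_table = logistic_table,
                 predictive_table = predictive_table,
                 scored = scored,
                 metadata = list(n_total = nrow(cohort),
                                 n_im_present = nrow(imp),
                                 provenance = attr(cohort, "provenance"),
                                 conf = conf,
                                 pcr_rate_total =
                                   round_half_up(100 * mean(cohort$pcr)),
                                 pcr_rate_im_present = if (has_im)
                                   round_half_up(100 * mean(imp$pcr), 1))),
            class = "iscr_report")
}

#' @export
print.iscr_report <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("ISCR report: %d patients (%d with evaluable IM), pCR %d%%\n",
              md$n_total, md$n_im_present, md$pcr_rate_total))
  cat("\nCut-offs (Youden):\n")
  print(as.data.frame(x$cutoff_table), digits = 4)
  if (!is.null(x$distribution_table)) {
    cat("\nISCR distribution (IM-present):\n")
    print(x$distribution_table, row.names = FALSE)
  }
  if (!is.null(x$logistic_table)) {
    f <- x$logistic_table$iscr_binary
    cat(sprintf("\nBinary ISCR (0-2 vs 3-4) logistic: OR %.2f (95%% CI %.2f-%.2f), Wald p %.3g\n",
                f$odds_ratio, f$or_ci[1], f$or_ci[2], f$p_values[["x"]]))
  }
  if (!is.null(x$association_tables$iscr_tier)) {
    pr <- x$association_tables$iscr_tier$proportions
    cat(sprintf("pCR by tier: %s\n",
                paste(sprintf("%s %d%%", pr$group, pr$percent),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Serialize a report bundle to JSON
#'
#' Canonical-key-order JSON rendering of the report's tables, suitable for
#' byte-identical re-run comparison.
#'
#' @param report an `iscr_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "iscr_report"))
  simplify <- function(x) {
    if (inherits(x, "contingency_table")) {
      list(rows = rownames(x), cols = colnames(x),
           counts = unclass(unname(x)))
    } else if (inherits(x, c("logistic_fit", "predictive_values",
                             "association_result"))) {
      lapply(unclass(x), unname)
    } else if (is.data.frame(x)) {
      as.list(x)
    } else if (is.list(x)) {
      lapply(x, simplify)
    } else {
      x
    }
  }
  bundle <- simplify(report[c("summary_table", "cutoff_table",
                              "distribution_table", "association_tables",
                              "logistic_table", "predictive_table",
                              "metadata")])
  bundle <- bundle[order(names(bundle))]
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}
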