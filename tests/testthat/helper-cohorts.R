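# Shared test fixtures, built in code.

# A hand-sized cohort with known structure: ids P01..Pn, fixed covariates,
# densities supplied by the caller.
make_cohort <- function(cd3_ct, cd8_ct, cd3_im, cd8_im, pcr,
                        subtype = "TNBC") {
  n <- length(cd3_ct)
  cohort_table(data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    subtype = rep_len(subtype, n),
    tumor_size = rep_len("T2", n), nodal_status = rep_len("negative", n),
    stage_group = rep_len("IIA", n),
    er_positive = rep_len(FALSE, n), pr_positive = rep_len(FALSE, n),
    her2_positive = rep_len(FALSE, n),
    ki67_percent = rep_len(40, n), menopausal = rep_len("post", n),
    cd3_ct = cd3_ct, cd8_ct = cd8_ct, cd3_im = cd3_im, cd8_im = cd8_im,
    pcr = pcr))
}

# Default synthetic parameter set, built once per test run (calibration is
# deterministic but not free).
default_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- iscr::synthetic_params()
    cache
  }
})

# Brute-force two-sided Fisher p for a 2x2 table via the hypergeometric
# point-probability rule; independent of the package implementation.
fisher_2x2_oracle <- function(m) {
  k <- sum(m[1, ]); K <- sum(m[, 1]); n <- sum(m)
  support <- max(0, k + K - n):min(k, K)
  probs <- dhyper(support, K, n - K, k)
  min(1, sum(probs[probs <= dhyper(m[1, 1], K, n - K, k) * (1 + 1e-7)]))
}
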