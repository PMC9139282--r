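# Association statistics against closed forms and base-R oracles.

test_that("Pearson chi-square reproduces the cohort-comparability statistic", {
  res <- pearson_chi2(rbind(c(40, 23, 12), c(13, 9, 6)))
  expect_equal(round(res$statistic, 3), 0.547)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.7607, tolerance = 1e-4)
})

test_that("chi-square is zero for proportional rows", {
  expect_equal(pearson_chi2(rbind(c(10, 20), c(20, 40)))$statistic, 0)
})

test_that("2x2 chi-square matches the closed-form identity", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2)
    n <- sum(m)
    closed <- n * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      prod(rowSums(m), colSums(m))
    expect_equal(pearson_chi2(m)$statistic, closed, tolerance = 1e-10)
  }
})

test_that("chi-square is invariant under permutation and transposition", {
  m <- rbind(c(12, 5, 9), c(3, 14, 8))
  base <- pearson_chi2(m)$statistic
  expect_equal(pearson_chi2(m[, c(3, 1, 2)])$statistic, base)
  expect_equal(pearson_chi2(m[c(2, 1), ])$statistic, base)
  expect_equal(pearson_chi2(t(m))$statistic, base)
  # cross-check against the base-R implementation
  expect_equal(base, unname(chisq.test(m, correct = FALSE)$statistic))
})

test_that("Fisher exact reproduces the printed HER2 association p-value", {
  res <- fisher_exact(rbind(c(9, 9), c(36, 49)))
  expect_equal(round(res$p_value, 3), 0.607)
})

test_that("Fisher exact handles canonical small tables", {
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5)))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(rbind(c(1, 1), c(1, 1)))$p_value, 1)
  expect_error(fisher_exact(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("Fisher exact equals base-R fisher.test on random 2x2 tables", {
  set.seed(13)
  for (i in 1:60) {
    m <- matrix(sample(0:12, 4, replace = TRUE), 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact(m)$p_value, fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("Fisher exact equals the hypergeometric oracle for all totals <= 14", {
  worst <- 0
  for (n in 2:14) {
    for (r1 in 1:(n - 1)) {
      for (c1 in 1:(n - 1)) {
        a_min <- max(0, r1 + c1 - n)
        a_max <- min(r1, c1)
        for (a in a_min:a_max) {
          m <- rbind(c(a, r1 - a), c(c1 - a, n - r1 - c1 + a))
          worst <- max(worst, abs(fisher_exact(m)$p_value -
                                    fisher_2x2_oracle(m)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("Freeman-Halton enumeration matches fisher.test on r x c tables", {
  tables <- list(rbind(c(3, 7, 2), c(5, 1, 6)),
                 rbind(c(40, 23, 12), c(13, 9, 6)),
                 rbind(c(2, 4), c(5, 1), c(3, 3)),
                 rbind(c(10, 13), c(34, 31), c(1, 14)))
  for (m in tables) {
    expect_equal(fisher_exact(m)$p_value, fisher.test(m)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("Monte-Carlo Fisher path is seeded and close to the estimand", {
  m <- rbind(c(60, 80, 70), c(90, 65, 85))  # total 450 > enumeration limit
  r1 <- fisher_exact(m)
  r2 <- fisher_exact(m)
  expect_identical(r1$p_value, r2$p_value)  # fixed internal seed
  expect_match(r1$method_detail, "Monte-Carlo")
  expect_equal(r1$p_value,
               fisher.test(m, simulate.p.value = TRUE, B = 20000)$p.value,
               tolerance = 0.02)
})

test_that("Mann-Whitney handles separation, symmetry, and tie-free exactness", {
  sep <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$statistic, 0)
  expect_equal(sort(c(sep$u_a, sep$u_b)), c(0, 9))
  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 16 / 2)
  expect_gt(same$p_value, 0.99)
  # exact path agrees with base-R exact Wilcoxon on tie-free data
  set.seed(19)
  for (i in 1:10) {
    a <- sample(1:50, 5); b <- sample(51:100, 5) - sample(0:40, 5)
    if (length(unique(c(a, b))) < 10) next
    ours <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_true(ours$exact)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation matches wilcox.test with ties", {
  set.seed(37)
  for (i in 1:10) {
    a <- sample(1:10, 15, replace = TRUE)
    b <- sample(3:13, 18, replace = TRUE)
    ours <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_false(ours$exact)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$u_a, unname(ref$statistic))
  }
})

test_that("exact Mann-Whitney p is within 0.02 of the approximation at n = 10", {
  set.seed(41)
  a <- sample(1:8, 5, replace = TRUE)
  b <- sample(4:11, 5, replace = TRUE)
  exact_p <- mann_whitney(a, b)$p_value
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(exact_p - ref), 0.02)
})

test_that("odds ratio reproduces the binary-ISCR estimate and flags corrections", {
  expect_equal(odds_ratio(rbind(c(25, 11), c(6, 33)))$estimate, 12.5)
  expect_equal(odds_ratio(rbind(c(7, 3), c(7, 3)))$estimate, 1)
  corr <- odds_ratio(rbind(c(10, 0), c(5, 5)))
  expect_true(corr$corrected)
  expect_equal(corr$estimate, (10.5 * 5.5) / (0.5 * 5.5))
  plain <- odds_ratio(rbind(c(25, 11), c(6, 33)))
  expect_false(plain$corrected)
  expect_true(plain$ci_lower < 12.5 && 12.5 < plain$ci_upper)
})

test_that("predictive values reproduce the CD8-IM column", {
  pv <- predictive_values(reference_tables()$tables$cd8_im_pcr)
  expect_equal(pv$ppv_pct, 63.4)
  expect_equal(pv$npv_pct, 85.3)
  expect_equal(pv$tp, 26)
  expect_equal(pv$fn, 5)
  # intervals contain the point estimates
  expect_true(pv$ppv_ci[1] <= pv$ppv && pv$ppv <= pv$ppv_ci[2])
  expect_true(pv$npv_ci[1] <= pv$npv && pv$npv <= pv$npv_ci[2])
})

test_that("Clopper-Pearson bounds match binom.test and hit the edges", {
  pv <- predictive_values(tp = 10, fp = 0, tn = 5, fn = 5)
  expect_equal(pv$ppv, 1)
  expect_equal(unname(pv$ppv_ci[2]), 1)
  for (x in c(0, 3, 11, 26, 40)) {
    ci <- iscr:::clopper_pearson(x, 40)
    ref <- binom.test(x, 40)$conf.int
    expect_equal(unname(ci), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("Clopper-Pearson intervals achieve nominal coverage by simulation", {
  set.seed(53)
  n <- 40
  for (p in seq(0.1, 0.9, by = 0.2)) {
    x <- rbinom(1500, n, p)
    covered <- vapply(x, function(xi) {
      ci <- iscr:::clopper_pearson(xi, n)
      ci[1] <= p && p <= ci[2]
    }, logical(1))
    expect_gte(mean(covered), 0.95)
  }
})

test_that("logistic regression on a binary covariate equals the cross-product OR", {
  m <- rbind(c(25, 11), c(6, 33))  # exposure x outcome
  x <- rep(c(1, 1, 0, 0), times = c(25, 11, 6, 33))
  y <- rep(c(TRUE, FALSE, TRUE, FALSE), times = c(25, 11, 6, 33))
  fit <- logistic_univariate(x, y)
  expect_true(fit$converged)
  expect_equal(fit$odds_ratio, 12.5, tolerance = 1e-6)
  # Wald machinery against base-R glm
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-5)
})

test_that("logistic regression matches glm on continuous covariates", {
  set.seed(61)
  x <- rnorm(120)
  y <- runif(120) < plogis(-0.4 + 1.1 * x)
  fit <- logistic_univariate(x, y)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_false(fit$separated)
})

test_that("intercept-only fit recovers the logit of the prevalence", {
  y <- rep(c(TRUE, FALSE), times = c(30, 70))
  fit <- logistic_univariate(NULL, y)
  expect_equal(unname(fit$coefficients[1]), log(0.3 / 0.7), tolerance = 1e-8)
})

test_that("complete separation is flagged, not thrown", {
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  y <- c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)
  fit <- logistic_univariate(x, y)
  expect_true(fit$separated)
})

test_that("degenerate logistic inputs are rejected", {
  expect_error(logistic_univariate(rep(1, 10), rep(c(TRUE, FALSE), 5)),
               "constant")
  expect_error(logistic_univariate(rnorm(10), rep(TRUE, 10)), "both classes")
})

test_that("group proportions reproduce the printed response rates", {
  fx <- reference_tables()
  by_subtype <- proportions_from_table(fx$tables$subtype_pcr)
  expect_equal(by_subtype$percent[match(c("luminal", "HER2", "TNBC"),
                                        by_subtype$group)], c(9, 50, 62))
  by_tier <- proportions_from_table(fx$tables$iscr_tier_pcr)
  expect_equal(by_tier$percent[match(c("High", "Intermediate", "Low"),
                                     by_tier$group)], c(69, 50, 6))
  single <- proportions_by_group(rep("all", 4), rep(TRUE, 4))
  expect_equal(single$percent, 100)
})

test_that("rounding of reported percentages is half-up", {
  expect_equal(round_half_up(43.5), 44)
  expect_equal(round_half_up(6.45), 6)     # 6.45 is below 6.5
  expect_equal(round_half_up(62.264), 62)
  expect_equal(round_half_up(85.294, 1), 85.3)
  expect_equal(round_half_up(-2.5), -3)
})

test_that("AUC equals the Mann-Whitney U statistic across modules", {
  set.seed(71)
  vals <- sample(1:15, 40, replace = TRUE)
  labs <- runif(40) < plogis((vals - 8) / 3)
  if (any(labs) && !all(labs)) {
    res <- mann_whitney(vals[labs], vals[!labs])
    n1 <- sum(labs); n2 <- sum(!labs)
    expect_equal(auc(roc_curve(vals, labs)), res$u_a / (n1 * n2),
                 tolerance = 1e-12)
  }
})
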