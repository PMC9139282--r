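# Association statistics: Pearson chi-square, Fisher exact (hypergeometric
# enumeration, Freeman-Halton for r x c), Mann-Whitney U, odds ratios,
# predictive values with exact Clopper-Pearson intervals, and univariate
# logistic regression by IRLS. Implemented from first principles; base-R
# distribution functions (pchisq, dhyper, pnorm, qbeta) evaluate the
# reference distributions.

association_result <- function(method, statistic, p_value, df = NA_real_,
                               estimate = NA_real_, ...) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p_value = p_value, estimate = estimate), list(...)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f%s, p = %.4g%s\n", x$method, x$statistic,
              if (!is.na(x$df)) sprintf(", df = %d", as.integer(x$df)) else "",
              x$p_value,
              if (!is.na(x$estimate)) sprintf(", estimate = %.4g", x$estimate)
              else ""))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Classic chi-square on an r x c table: sum (O - E)^2 / E with expectations
#' from the margins, (r-1)(c-1) degrees of freedom, no continuity
#' correction (the convention under which the published cohort-comparability
#' statistic of 0.547 reproduces exactly).
#'
#' @param table a [contingency_table()] or count matrix with positive row
#'   and column margins.
#' @return an `association_result` with `statistic`, `df`, `p_value` and
#'   the `expected` matrix.
#' @export
pearson_chi2 <- function(table) {
  m <- as_contingency(table)
  fail_if(any(rowSums(m) == 0) || any(colSums(m) == 0),
          "all row and column margins must be positive")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - expected)^2 / expected)
  df <- (nrow(m) - 1) * (ncol(m) - 1)
  association_result("Pearson chi-square", stat,
                     stats::pchisq(stat, df, lower.tail = FALSE), df = df,
                     expected = expected)
}

# log multivariate-hypergeometric probability of a table given its margins
log_table_prob <- function(m) {
  sum(lgamma(rowSums(m) + 1)) + sum(lgamma(colSums(m) + 1)) -
    lgamma(sum(m) + 1) - sum(lgamma(m + 1))
}

# All tables with the given margins, visited depth-first row by row;
# f(table) is called on each. Used for the Freeman-Halton enumeration.
visit_margin_tables <- function(row_tot, col_tot, f) {
  r <- length(row_tot)
  recurse <- function(filled, col_left) {
    i <- nrow(filled) + 1
    if (i == r) {
      f(rbind(filled, col_left))
      return(invisible(NULL))
    }
    fill_row <- function(row_so_far, j) {
      left <- row_tot[i] - sum(row_so_far)
      if (j == length(col_tot)) {
        if (left <= col_left[j]) {
          row <- c(row_so_far, left)
          recurse(rbind(filled, row), col_left - row)
        }
        return(invisible(NULL))
      }
      hi <- min(col_left[j], left)
      lo <- max(0, left - sum(col_left[(j + 1):length(col_tot)]))
      for (v in lo:hi) fill_row(c(row_so_far, v), j + 1)
    }
    fill_row(integer(0), 1)
  }
  recurse(matrix(integer(0), nrow = 0, ncol = length(col_tot)), col_tot)
}

#' Fisher exact test
#'
#' Two-sided exact test on a contingency table with fixed margins. For 2x2
#' tables the null distribution is hypergeometric and the two-sided p-value
#' sums the probabilities of all tables no more probable than the observed
#' one (point-probability rule). For r x c tables the Freeman-Halton
#' extension is computed by full enumeration when the grand total is at
#' most `enum_limit`; beyond that a seeded Monte-Carlo estimate over
#' Patefield-sampled tables is returned, with the repetition count reported.
#'
#' @param table a [contingency_table()] or count matrix, nondegenerate
#'   margins.
#' @param enum_limit largest grand total for which r x c enumeration is
#'   attempted (default 200).
#' @param mc_reps,mc_seed Monte-Carlo repetitions and seed for larger
#'   tables.
#' @return an `association_result`; for 2x2 the `estimate` is the
#'   sample odds ratio, and `method_detail` records
#'   enumeration vs Monte-Carlo for r x c tables.
#' @export
fisher_exact <- function(table, enum_limit = 200, mc_reps = 100000,
                         mc_seed = 194) {
  m <- as_contingency(table)
  fail_if(any(rowSums(m) == 0) || any(colSums(m) == 0),
          "degenerate margins: every row and column must have a positive total")
  tol <- 1 + 1e-7
  if (nrow(m) == 2 && ncol(m) == 2) {
    k <- rowSums(m)[1]
    K <- colSums(m)[1]
    n <- sum(m)
    support <- max(0, k + K - n):min(k, K)
    probs <- stats::dhyper(support, K, n - K, k)
    p_obs <- stats::dhyper(m[1, 1], K, n - K, k)
    p <- min(1, sum(probs[probs <= p_obs * tol]))
    or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
    return(association_result("Fisher exact", p_obs, p, estimate = or,
                              method_detail = "hypergeometric enumeration"))
  }
  lp_obs <- log_table_prob(m)
  if (sum(m) <= enum_limit) {
    total <- 0
    visit_margin_tables(rowSums(m), colSums(m), function(tab) {
      lp <- log_table_prob(tab)
      if (lp <= lp_obs + log(tol)) total <<- total + exp(lp)
    })
    p <- min(1, total)
    detail <- "Freeman-Halton enumeration"
  } else {
    sims <- with_seed(mc_seed,
                      stats::r2dtable(mc_reps, rowSums(m), colSums(m)))
    hits <- sum(vapply(sims, function(tab) {
      log_table_prob(tab) <= lp_obs + log(tol)
    }, logical(1)))
    p <- (hits + 1) / (mc_reps + 1)
    detail <- sprintf("Monte-Carlo, %d reps, seed %d", mc_reps, mc_seed)
  }
  association_result("Fisher exact", exp(lp_obs), p, method_detail = detail)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midrank handling of ties. The
#' two-sided p-value uses the normal approximation with tie correction and
#' continuity correction, except for small samples (combined n <= 12) where
#' the full permutation distribution of U is enumerated.
#'
#' @param a,b numeric vectors, both non-empty; missing values dropped.
#' @return an `association_result` whose `statistic` is min(U_A, U_B), with
#'   components `u_a`, `u_b`, `polarity` (which group attains the minimum)
#'   and `exact` (whether the enumeration path was used).
#' @export
mann_whitney <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  fail_if(length(a) == 0 || length(b) == 0, "both groups must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  u_a <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_b <- n1 * n2 - u_a
  u <- min(u_a, u_b)
  center <- n1 * n2 / 2
  if (n <= 12) {
    dev_obs <- abs(u_a - center)
    idx <- utils::combn(n, n1)
    devs <- apply(idx, 2, function(ix) {
      abs(sum(r[ix]) - n1 * (n1 + 1) / 2 - center)
    })
    p <- mean(devs >= dev_obs - 1e-9)
    exact <- TRUE
  } else {
    ties <- table(pooled)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- u_a - center
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  association_result("Mann-Whitney U", u, p, u_a = u_a, u_b = u_b,
                     polarity = if (u_a <= u_b) "A" else "B", exact = exact)
}

#' Odds ratio with Wald confidence interval
#'
#' Cross-product odds ratio of a 2x2 table, with a 95% Wald interval on the
#' log scale (SE = sqrt(1/a + 1/b + 1/c + 1/d)). When any cell is zero the
#' Haldane-Anscombe correction (+0.5 to every cell) is applied and flagged.
#'
#' @param table 2x2 [contingency_table()] or matrix, rows = exposure,
#'   columns = outcome.
#' @return an `association_result` with `estimate` = OR, `ci_lower`,
#'   `ci_upper`, `log_or`, `se_log_or`, `corrected`.
#' @export
odds_ratio <- function(table) {
  m <- as_contingency(table)
  fail_if(nrow(m) != 2 || ncol(m) != 2, "odds_ratio needs a 2x2 table")
  corrected <- any(m == 0)
  w <- m + if (corrected) 0.5 else 0
  or <- (w[1, 1] * w[2, 2]) / (w[1, 2] * w[2, 1])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(0.975)
  association_result("Odds ratio", log(or),
                     2 * stats::pnorm(-abs(log(or) / se)),
                     estimate = or,
                     ci_lower = exp(log(or) - z * se),
                     ci_upper = exp(log(or) + z * se),
                     log_or = log(or), se_log_or = se, corrected = corrected)
}

# Exact Clopper-Pearson binomial interval via beta quantiles.
clopper_pearson <- function(x, n, conf = 0.95) {
  al <- (1 - conf) / 2
  lower <- if (x == 0) 0 else stats::qbeta(al, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - al, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Positive and negative predictive values
#'
#' PPV = tp / (tp + fp) and NPV = tn / (tn + fn) with exact 95%
#' Clopper-Pearson intervals. Accepts either the four counts or a 2x2 table
#' with rows test-high/test-low and columns outcome-positive (pCR) /
#' outcome-negative.
#'
#' @param tp,fp,tn,fn nonnegative integer counts; alternatively pass a 2x2
#'   table as `tp` and leave the rest missing.
#' @param conf confidence level (default 0.95).
#' @return a `predictive_values` list: counts, `ppv`, `npv` (fractions),
#'   `ppv_ci`, `npv_ci`, and `ppv_pct`, `npv_pct` rounded half-up to one
#'   decimal, the convention of the published predictive-value table.
#' @examples
#' predictive_values(reference_tables()$tables$cd8_im_pcr)
#' @export
predictive_values <- function(tp, fp = NULL, tn = NULL, fn = NULL,
                              conf = 0.95) {
  if (is.matrix(tp) || inherits(tp, "contingency_table")) {
    m <- as_contingency(tp)
    fail_if(nrow(m) != 2 || ncol(m) != 2, "predictive_values needs 2x2 counts")
    fn <- m[2, 1]; tn <- m[2, 2]; fp <- m[1, 2]; tp <- m[1, 1]
  }
  fail_if(any(c(tp, fp, tn, fn) < 0), "counts must be nonnegative")
  fail_if(tp + fp == 0, "no test-positive patients: PPV undefined")
  fail_if(tn + fn == 0, "no test-negative patients: NPV undefined")
  ppv <- tp / (tp + fp)
  npv <- tn / (tn + fn)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 ppv = ppv, npv = npv,
                 ppv_ci = clopper_pearson(tp, tp + fp, conf),
                 npv_ci = clopper_pearson(tn, tn + fn, conf),
                 ppv_pct = round_half_up(100 * ppv, 1),
                 npv_pct = round_half_up(100 * npv, 1),
                 conf = conf),
            class = "predictive_values")
}

#' @export
print.predictive_values <- function(x, ...) {
  cat(sprintf("PPV %.1f%% (%.1f-%.1f), NPV %.1f%% (%.1f-%.1f) [%d%% CI]\n",
              x$ppv_pct, 100 * x$ppv_ci[1], 100 * x$ppv_ci[2],
              x$npv_pct, 100 * x$npv_ci[1], 100 * x$npv_ci[2],
              round(100 * x$conf)))
  invisible(x)
}

#' Univariate logistic regression by IRLS
#'
#' Maximum-likelihood logistic fit of a binary outcome on a single
#' covariate (or intercept only), by iteratively reweighted least squares:
#' convergence on a log-likelihood change below `tol`, at most `max_iter`
#' iterations. Complete or quasi-complete separation is detected (diverging
#' coefficients with fitted probabilities at the boundary) and reported as
#' a flag rather than an error. With a binary covariate and all four cells
#' positive, exp(slope) equals the cross-product odds ratio.
#'
#' @param x covariate: numeric, logical, or a two-level factor; `NULL` for
#'   an intercept-only fit. Must be non-constant when present.
#' @param y logical outcome with both classes present.
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter maximum IRLS iterations (default 50).
#' @return a `logistic_fit` list: `coefficients`, `se`, `z`, `p_values`
#'   (Wald), `odds_ratio` and `or_ci` (for the slope), `loglik`,
#'   `converged`, `iterations`, `separated`, `n`.
#' @export
logistic_univariate <- function(x, y, tol = 1e-8, max_iter = 50) {
  y <- as.logical(y)
  keep <- !is.na(y) & (if (is.null(x)) TRUE else !is.na(x))
  y <- y[keep]
  fail_if(!any(y) || all(y), "outcome must contain both classes")
  if (is.null(x)) {
    X <- matrix(1, nrow = length(y), dimnames = list(NULL, "(Intercept)"))
  } else {
    x <- x[keep]
    if (is.factor(x)) {
      fail_if(nlevels(droplevels(x)) != 2,
              "factor covariates must have exactly two observed levels")
      x <- as.numeric(droplevels(x)) - 1
    }
    x <- as.numeric(x)
    fail_if(stats::var(x) == 0, "covariate is constant")
    X <- cbind("(Intercept)" = 1, x = x)
  }
  yy <- as.numeric(y)
  beta <- rep(0, ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (yy - mu) / w
    fit <- tryCatch(solve(crossprod(X, w * X), crossprod(X, w * z)),
                    error = function(e) NULL)
    if (is.null(fit)) break
    beta <- drop(fit)
    eta <- drop(X %*% beta)
    ll <- sum(yy * eta - log1p(exp(eta)))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  separated <- max(abs(beta)) > 12 &&
    all(abs(yy - mu)[abs(eta) > 10] < 1e-3)
  w <- pmax(mu * (1 - mu), 1e-12)
  vcov <- tryCatch(solve(crossprod(X, w * X)), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  se <- sqrt(diag(vcov))
  zstat <- beta / se
  pv <- 2 * stats::pnorm(-abs(zstat))
  names(beta) <- names(se) <- names(zstat) <- names(pv) <- colnames(X)
  or <- if (ncol(X) > 1) exp(beta[["x"]]) else NA_real_
  or_ci <- if (ncol(X) > 1) {
    exp(beta[["x"]] + c(-1, 1) * stats::qnorm(0.975) * se[["x"]])
  } else {
    c(NA_real_, NA_real_)
  }
  structure(list(coefficients = beta, se = se, z = zstat, p_values = pv,
                 odds_ratio = unname(or), or_ci = or_ci,
                 loglik = sum(yy * eta - log1p(exp(eta))),
                 converged = converged, iterations = iter,
                 separated = separated, n = length(yy)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "logistic fit (n = %d, %d IRLS iterations%s%s)\n", x$n, x$iterations,
    if (x$converged) ", converged" else ", NOT converged",
    if (x$separated) ", separation detected" else ""))
  tab <- data.frame(coef = x$coefficients, se = x$se, z = x$z, p = x$p_values)
  print(round(tab, 5))
  if (!is.na(x$odds_ratio)) {
    cat(sprintf("OR = %.4g (95%% CI %.4g-%.4g)\n", x$odds_ratio,
                x$or_ci[1], x$or_ci[2]))
  }
  invisible(x)
}

#' Outcome proportions by group
#'
#' Per-group outcome fractions with raw counts and half-up integer-rounded
#' percentages, the format of the published response-rate tables.
#'
#' @param groups group labels (factor or character).
#' @param outcome logical outcome vector.
#' @return data frame with columns `group`, `n`, `events`, `fraction`,
#'   `percent` (integer, half-up).
#' @export
proportions_by_group <- function(groups, outcome) {
  fail_if(length(groups) == 0, "empty input")
  stopifnot(length(groups) == length(outcome))
  keep <- !is.na(groups) & !is.na(outcome)
  g <- factor(groups[keep])
  o <- as.logical(outcome[keep])
  n <- as.integer(table(g))
  ev <- as.integer(tapply(o, g, sum))
  data.frame(group = levels(g), n = n, events = ev, fraction = ev / n,
             percent = round_half_up(100 * ev / n), row.names = NULL)
}

#' @rdname proportions_by_group
#' @param table contingency table whose first column counts events (e.g.
#'   pCR) and whose rows are the groups.
#' @param positive_col index of the event column (default 1).
#' @export
proportions_from_table <- function(table, positive_col = 1) {
  m <- as_contingency(table)
  n <- rowSums(m)
  ev <- m[, positive_col]
  data.frame(group = rownames(m), n = as.integer(n), events = as.integer(ev),
             fraction = ev / n, percent = round_half_up(100 * ev / n),
             row.names = NULL)
}
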