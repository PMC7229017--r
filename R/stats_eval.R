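# The statistical battery: mixed-model association of pose error with
# retained length (ML fits, nested-model likelihood-ratio test), rank tests
# comparing automatic vs simulated-manual placement, and the two-way
# absolute-agreement ICC for observer reproducibility.

#' Linear mixed model: pose error versus retained length
#'
#' Fits `response ~ length_pct + (1 | bone_id)` by maximum likelihood (ML,
#' not REML: REML likelihoods are not comparable across fixed-effect
#' structures), refits without the fixed effect, and compares the two with a
#' 1-df chi-square likelihood-ratio test. `length_pct` enters as a continuous
#' covariate by default; set `categorical = TRUE` for factor coding.
#'
#' @param records data frame with columns `bone_id`, `length_pct` and the
#'   response; rows with missing response are dropped.
#' @param response name of the response column (one of the pose-error
#'   fields, e.g. `"phi_err"`).
#' @param fixed name of the fixed-effect column (default `"length_pct"`;
#'   covariate hooks pass e.g. `"age_years"`).
#' @param categorical treat the fixed effect as a factor.
#' @return An object of class `lmm_result`: `fixed_coefficients` (matrix with
#'   estimate and standard error), `random_intercept_variance`,
#'   `residual_variance`, `loglik_full`, `loglik_reduced`, `lrt_statistic`,
#'   `lrt_df`, `p_value`.
#' @export
fit_lmm_length <- function(records, response = "phi_err",
                           fixed = "length_pct", categorical = FALSE) {
  if (!is.data.frame(records) ||
      !all(c("bone_id", fixed, response) %in% names(records))) {
    abort_radcs(sprintf("records must contain bone_id, %s and %s",
                        fixed, response), "radcs_validation_error")
  }
  d <- records[is.finite(records[[response]]), , drop = FALSE]
  if (length(unique(d$bone_id)) < 2L) {
    abort_radcs("need >= 2 bones for a random intercept",
                "radcs_degenerate_design")
  }
  if (length(unique(d[[fixed]])) < 2L) {
    abort_radcs(sprintf("fixed effect '%s' has a single level: degenerate design",
                        fixed), "radcs_degenerate_design")
  }
  d$.y <- d[[response]]
  d$.x <- if (categorical) factor(d[[fixed]]) else as.numeric(d[[fixed]])
  full <- lme4::lmer(.y ~ .x + (1 | bone_id), data = d, REML = FALSE)
  red <- lme4::lmer(.y ~ 1 + (1 | bone_id), data = d, REML = FALSE)
  ll_f <- as.numeric(logLik(full))
  ll_r <- as.numeric(logLik(red))
  lrt <- max(0, 2 * (ll_f - ll_r))
  df <- attr(logLik(full), "df") - attr(logLik(red), "df")
  co <- summary(full)$coefficients[, 1:2, drop = FALSE]
  vc <- as.data.frame(lme4::VarCorr(full))
  structure(list(
    fixed_coefficients = co,
    random_intercept_variance = vc$vcov[vc$grp == "bone_id"][1L],
    residual_variance = vc$vcov[vc$grp == "Residual"][1L],
    loglik_full = ll_f,
    loglik_reduced = ll_r,
    lrt_statistic = lrt,
    lrt_df = df,
    p_value = pchisq(lrt, df, lower.tail = FALSE)
  ), class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> LRT chi2(%d) = %.3f, p = %.3g\n",
              x$lrt_df, x$lrt_statistic, x$p_value))
  invisible(x)
}

# exact null distribution of a linear rank statistic: sum of `scores` over
# all choose(N, na) subsets of size na
enumerate_rank_statistic <- function(scores, na) {
  splits <- combn(length(scores), na)
  colSums(matrix(scores[splits], nrow = na))
}

two_sided_exact_p <- function(stat_dist, observed, tol = 1e-9) {
  n <- length(stat_dist)
  p_lo <- sum(stat_dist <= observed + tol) / n
  p_hi <- sum(stat_dist >= observed - tol) / n
  min(1, 2 * min(p_lo, p_hi))
}

#' Mann-Whitney U test
#'
#' Two-sided location test. For pooled sample sizes up to 12 without ties the
#' p-value is computed by exhaustive enumeration of all group assignments;
#' otherwise a normal approximation with tie correction is used (no
#' continuity correction).
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return An object of class `rank_test_result`: `statistic` (U for
#'   `sample_a`), `p_value`, `method_label`, `exact`.
#' @export
mann_whitney <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    abort_radcs("both samples must be non-empty", "radcs_validation_error")
  }
  na <- length(sample_a)
  nb <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0L
  if (na + nb <= 12L && !ties) {
    dist <- enumerate_rank_statistic(r, na) - na * (na + 1) / 2
    p <- two_sided_exact_p(dist, u)
    exact <- TRUE
  } else {
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    n <- na + nb
    sig2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) /
                              (n * (n - 1)))
    p <- if (sig2 <= 0) 1 else 2 * pnorm(-abs(u - mu) / sqrt(sig2))
    p <- min(1, p)
    exact <- FALSE
  }
  structure(list(statistic = u, p_value = p,
                 method_label = "Mann-Whitney U (two-sided)", exact = exact),
            class = "rank_test_result")
}

ansari_scores <- function(pooled) {
  r <- rank(pooled)
  n <- length(pooled)
  pmin(r, n + 1 - r)
}

#' Ansari-Bradley dispersion test
#'
#' Two-sided rank test for equality of scale. Ansari-Bradley scores rank
#' observations from both ends of the pooled sample inward; the statistic is
#' the score sum of the first sample. Exact enumeration for pooled sizes up
#' to 12 without ties, otherwise a normal approximation on the (midrank)
#' scores.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return An object of class `rank_test_result`.
#' @export
ansari_bradley <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    abort_radcs("both samples must be non-empty", "radcs_validation_error")
  }
  na <- length(sample_a)
  nb <- length(sample_b)
  pooled <- c(sample_a, sample_b)
  s <- ansari_scores(pooled)
  ab <- sum(s[seq_len(na)])
  ties <- anyDuplicated(pooled) > 0L
  if (na + nb <= 12L && !ties) {
    dist <- enumerate_rank_statistic(s, na)
    p <- two_sided_exact_p(dist, ab)
    exact <- TRUE
  } else {
    n <- na + nb
    mu <- na * mean(s)
    sig2 <- na * nb * sum((s - mean(s))^2) / (n * (n - 1))
    p <- if (sig2 <= 0) 1 else 2 * pnorm(-abs(ab - mu) / sqrt(sig2))
    p <- min(1, p)
    exact <- FALSE
  }
  structure(list(statistic = ab, p_value = p,
                 method_label = "Ansari-Bradley (two-sided)", exact = exact),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.3f, p = %.4g%s\n", x$method_label,
              x$statistic, x$p_value, if (x$exact) " (exact)" else ""))
  invisible(x)
}

#' Two-way absolute-agreement intraclass correlation, single rater
#'
#' ICC(A,1) from the two-way ANOVA mean squares of a complete
#' subjects-by-raters table:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, rater and
#' residual mean squares, `n` subjects and `k` raters. Absolute agreement
#' penalizes systematic rater bias (unlike consistency ICC). The agreement
#' band follows the Landis-Koch cut points 0.20/0.40/0.60/0.80.
#'
#' @param table numeric matrix, subjects in rows, raters in columns; complete
#'   (no missing cells), at least 2 x 2.
#' @return An object of class `icc_result`: `icc`, `model_label`,
#'   `agreement_band`, and the mean squares.
#' @export
icc_two_way_absolute <- function(table) {
  m <- as.matrix(table)
  if (any(!is.finite(m))) {
    abort_radcs("ICC table must be complete (no missing cells)",
                "radcs_validation_error")
  }
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) {
    abort_radcs("ICC needs >= 2 subjects and >= 2 raters",
                "radcs_validation_error")
  }
  g <- mean(m)
  msr <- k * sum((rowMeans(m) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - g)^2) / (k - 1)
  sst <- sum((m - g)^2)
  mse <- (sst - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (abs(denom) < 1e-300) 1 else (msr - mse) / denom
  band <- as.character(cut(icc, c(-Inf, 0.20, 0.40, 0.60, 0.80, Inf),
                           labels = c("poor", "fair", "moderate", "good",
                                      "perfect")))
  structure(list(icc = icc,
                 model_label = "ICC(A,1) two-way, absolute agreement",
                 agreement_band = band,
                 ms_rows = msr, ms_cols = msc, ms_error = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.3f (%s agreement)\n",
              x$icc, x$agreement_band))
  invisible(x)
}
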