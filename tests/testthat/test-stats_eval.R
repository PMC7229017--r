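test_that("Mann-Whitney exact p-values match exhaustive enumeration", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)      # 2/20 arrangements
  expect_true(r$exact)

  set.seed(17)
  for (sizes in list(c(3, 3), c(2, 8), c(4, 5), c(6, 6))) {
    a <- rnorm(sizes[1])
    b <- rnorm(sizes[2], 0.5)
    got <- mann_whitney(a, b)
    expect_equal(got$statistic, oracle_mw_u(a, b))
    ranks <- rank(c(a, b))
    expect_equal(got$p_value,
                 oracle_exact_rank_p(ranks, sizes[1],
                                     sum(ranks[seq_len(sizes[1])])))
    # base R second opinion on the statistic
    expect_equal(got$statistic,
                 unname(suppressWarnings(wilcox.test(a, b)$statistic)))
  }
})

test_that("Mann-Whitney approximation handles ties and large samples", {
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 4.5)
  expect_equal(r$p_value, 1)
  expect_false(r$exact)

  set.seed(23)
  a <- rnorm(85, 3, 1)
  b <- rnorm(5, 0, 1)
  expect_lt(mann_whitney(a, b)$p_value, 0.001)
  expect_equal(mann_whitney(rep(1, 20), rep(1, 20))$p_value, 1)
})

test_that("Ansari-Bradley matches hand scores and enumeration", {
  got <- ansari_bradley(c(-10, 10), c(-1, 0, 1))
  # pooled ranks 1..5 -> scores 1,2,3,2,1; sample_a holds the two extremes
  expect_equal(got$statistic, 2)
  sc <- oracle_ab_scores(c(-10, 10, -1, 0, 1))
  expect_equal(got$p_value, oracle_exact_rank_p(sc, 2, 2))

  set.seed(29)
  for (sizes in list(c(4, 4), c(3, 7), c(5, 5))) {
    a <- rnorm(sizes[1])
    b <- rnorm(sizes[2])
    got <- ansari_bradley(a, b)
    sc <- oracle_ab_scores(c(a, b))
    expect_equal(got$p_value,
                 oracle_exact_rank_p(sc, sizes[1],
                                     sum(sc[seq_len(sizes[1])])))
    expect_equal(got$statistic,
                 unname(suppressWarnings(ansari.test(a, b)$statistic)))
  }

  same <- ansari_bradley(c(1.2, 3.4, 2.2, 4.1), c(1.3, 3.3, 2.1, 4.0))
  expect_gt(same$p_value, 0.5)
})

test_that("Ansari-Bradley detects scale differences", {
  set.seed(31)
  hits <- vapply(1:50, function(i) {
    a <- rnorm(50, 0, 5)
    b <- rnorm(50, 0, 1)
    ansari_bradley(a, b)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("ICC(A,1) matches the ANOVA mean-squares oracle", {
  agree <- matrix(rep(c(1, 5, 9, 13), 3), ncol = 3)
  r <- icc_two_way_absolute(agree)
  expect_equal(r$icc, 1)
  expect_equal(r$agreement_band, "perfect")

  hand <- rbind(c(9, 2, 5), c(6, 1, 3), c(8, 4, 6), c(7, 1, 2))
  expect_equal(icc_two_way_absolute(hand)$icc, oracle_icc_a1(hand))

  # absolute agreement penalizes a rater offset; consistency does not
  shifted <- agree
  shifted[, 2] <- shifted[, 2] + 4
  expect_lt(icc_two_way_absolute(shifted)$icc,
            oracle_icc_consistency(shifted))

  set.seed(37)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    k <- sample(3:5, 1)
    m <- matrix(rnorm(n * k, rep(rnorm(n, 0, 2), k), 1), n, k)
    expect_equal(icc_two_way_absolute(m)$icc, oracle_icc_a1(m),
                 tolerance = 1e-9)
  }

  expect_error(icc_two_way_absolute(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "radcs_validation_error")
  expect_error(icc_two_way_absolute(matrix(1:3, 3, 1)),
               class = "radcs_validation_error")
})

test_that("Landis-Koch bands follow the cut points", {
  expect_equal(icc_two_way_absolute(rbind(c(1, 1), c(2, 2), c(3, 3)))$
                 agreement_band, "perfect")
  # uncorrelated raters on near-constant subjects: ICC near zero -> poor
  set.seed(47)
  noise <- matrix(rnorm(40), 10, 4)
  r <- icc_two_way_absolute(noise)
  expect_lt(r$icc, 0.20)
  expect_equal(r$agreement_band, "poor")
})

test_that("fit_lmm_length recovers a known slope and rejects degenerate designs", {
  set.seed(41)
  bones <- sprintf("b%02d", 1:85)
  lengths <- seq(10, 100, 10)
  d <- expand.grid(bone_id = bones, length_pct = lengths,
                   stringsAsFactors = FALSE)
  u <- rnorm(85, 0, 2)
  names(u) <- bones
  slope <- 0.5 / 10                       # 0.5 per 10% step
  d$phi_err <- 3 + slope * d$length_pct + u[d$bone_id] + rnorm(nrow(d), 0, 1)
  fit <- fit_lmm_length(d, "phi_err")
  expect_equal(unname(fit$fixed_coefficients[2, 1]), slope, tolerance = 0.1)
  expect_lt(fit$p_value, 1e-6)
  expect_gte(fit$lrt_statistic, 0)
  expect_lte(fit$loglik_reduced, fit$loglik_full + 1e-6)
  expect_equal(fit$lrt_df, 1L)

  d1 <- d[d$length_pct == 50, ]
  expect_error(fit_lmm_length(d1, "phi_err"),
               class = "radcs_degenerate_design")
  d2 <- d[d$bone_id == "b01", ]
  expect_error(fit_lmm_length(d2, "phi_err"),
               class = "radcs_degenerate_design")
  expect_error(fit_lmm_length(data.frame(a = 1), "phi_err"),
               class = "radcs_validation_error")
})

test_that("categorical coding and covariate hooks work", {
  set.seed(43)
  d <- expand.grid(bone_id = sprintf("b%02d", 1:20),
                   length_pct = seq(10, 100, 10), stringsAsFactors = FALSE)
  d$phi_err <- rnorm(nrow(d), 5, 1)
  d$age_years <- rep(runif(20, 10, 60), 10)
  fit <- fit_lmm_length(d, "phi_err", categorical = TRUE)
  expect_equal(fit$lrt_df, 9L)
  fit2 <- fit_lmm_length(d, "phi_err", fixed = "age_years")
  expect_gt(fit2$p_value, 0.001)   # no true age effect in this null draw
})

test_that("run_experiment has the designed shape and determinism", {
  coh <- generate_cohort(5, seed = 19, vertex_spacing = 3)
  rec <- run_experiment(coh, lengths = c(50L, 100L),
                        manual_noise = manual_noise_model(), seed = 2,
                        manual_bones = 5, n_observers = 3, n_replicates = 10)
  # 5 bones x 2 lengths auto + 5 x 2 x 3 x 10 manual
  expect_equal(sum(rec$method == "auto"), 10L)
  expect_equal(sum(rec$method == "manual_sim"), 300L)
  expect_false(any(rec$failed))

  # at 100% the automatic placement reproduces the reference exactly
  full_auto <- rec[rec$method == "auto" & rec$length_pct == 100, ]
  expect_true(all(abs(full_auto$d_err) < 1e-9))
  expect_true(all(abs(full_auto$phi_err) < 1e-9))

  rec2 <- run_experiment(coh, lengths = c(50L, 100L),
                         manual_noise = manual_noise_model(), seed = 2,
                         manual_bones = 5, n_observers = 3, n_replicates = 10)
  expect_identical(rec, rec2)

  s <- summarize_experiment(rec, "d_err")
  expect_true(all(c("length_pct", "method", "median", "q1", "q3") %in%
                    names(s)))
  expect_equal(nrow(s), 4L)
})
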