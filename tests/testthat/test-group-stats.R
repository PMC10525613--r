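# Nonparametric statistics: Mann-Whitney, Spearman, ROC, median split,
# summaries.  Cross-checks use independent oracles (enumeration, pair
# counting, pROC, cor.test).

test_that("Mann-Whitney U and exact p match hand enumerations", {
  r1 <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_two_sided, 0.1)  # 2/20 assignments as extreme
  expect_equal(r1$method, "exact")

  r2 <- mann_whitney_u(c(1, 3), c(2, 4))
  expect_equal(r2$statistic, 1)
  expect_equal(r2$p_two_sided, 2 / 3)

  x <- c(1, 2, 3, 4)
  r3 <- mann_whitney_u(x, x)
  expect_equal(r3$statistic, length(x)^2 / 2)
  expect_equal(r3$p_two_sided, 1)
})

test_that("exact p equals full enumeration for all shapes up to 6x6", {
  set.seed(31)
  for (rep in 1:40) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1000, nx + ny)  # tie-free
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    got <- mann_whitney_u(x, y)
    expect_equal(got$statistic, pair_count_U(x, y))
    expect_equal(got$p_two_sided, enum_mw_p(x, y), tolerance = 1e-12,
                 info = sprintf("nx=%d ny=%d rep=%d", nx, ny, rep))
  }
})

test_that("tied samples fall back to the corrected normal approximation", {
  x <- c(1, 2, 2, 3, 5, 5, 6, 7, 8, 9)
  y <- c(2, 3, 3, 4, 5, 6, 7, 7, 9, 10)
  got <- mann_whitney_u(x, y)
  expect_equal(got$method, "normal-approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  expect_equal(got$p_two_sided, ref$p.value)
  expect_equal(got$statistic, unname(ref$statistic))
})

test_that("Spearman matches closed forms and the t-approximation reference", {
  expect_equal(spearman_cor(1:3, c(1, 4, 9))$rho, 1)
  expect_equal(spearman_cor(1:3, c(9, 4, 1))$rho, -1)
  r <- spearman_cor(1:4, c(1, 3, 2, 4))
  expect_equal(r$rho, 0.8)  # 1 - 6*2/(4*15)
  ref <- suppressWarnings(stats::cor.test(1:4, c(1, 3, 2, 4),
                                          method = "spearman", exact = FALSE))
  expect_equal(r$p_two_sided, unname(ref$p.value), tolerance = 1e-12)
  # perfect correlation reports the permutation bound
  expect_equal(spearman_cor(1:5, (1:5)^3)$p_two_sided, 2 / factorial(5))
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("AUC follows the rank formula, its identities, and pROC", {
  r1 <- roc_auc(c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1),
                c(1, 1, 1, 0, 0, 0), 1, n_boot = 0)
  expect_equal(r1$auc, 1)
  r2 <- roc_auc(rep(0.5, 8), rep(c(1, 0), 4), 1, n_boot = 0)
  expect_equal(r2$auc, 0.5)
  r3 <- roc_auc(c(2, 4, 1, 3), c(1, 1, 0, 0), 1, n_boot = 0)
  expect_equal(r3$auc, 0.75)

  set.seed(41)
  for (i in 1:50) {
    n <- sample(6:30, 1)
    s <- stats::rnorm(n); lab <- sample(c(TRUE, FALSE), n, TRUE)
    if (length(unique(lab)) < 2) next
    got <- roc_auc(s, lab, TRUE, n_boot = 0)
    expect_equal(got$auc, pair_count_auc(s, lab), tolerance = 1e-12)
    # AUC-U identity
    U <- mann_whitney_u(s[lab], s[!lab])$statistic
    expect_equal(got$auc, U / (sum(lab) * sum(!lab)), tolerance = 1e-12)
    # complement under score negation (tie-free scores)
    expect_equal(roc_auc(-s, lab, TRUE, n_boot = 0)$auc, 1 - got$auc,
                 tolerance = 1e-12)
  }

  skip_if_not_installed("pROC")
  set.seed(42)
  s <- stats::rnorm(40); lab <- sample(0:1, 40, TRUE)
  got <- roc_auc(s, lab, 1, n_boot = 0)
  ref <- suppressMessages(as.numeric(pROC::auc(lab, s,
                                               direction = "<", quiet = TRUE)))
  expect_equal(got$auc, ref, tolerance = 1e-12)
})

test_that("ROC curves are monotone from (0,0) to (1,1) and CIs bracket the AUC", {
  set.seed(43)
  s <- c(stats::rnorm(20, 1), stats::rnorm(15))
  lab <- rep(c("case", "control"), c(20, 15))
  r <- roc_auc(s, lab, "case", n_boot = 500, seed = 7)
  expect_equal(r$curve$fpr[1], 0); expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0) && all(diff(r$curve$tpr) >= 0))
  expect_lte(r$ci_low, r$auc); expect_gte(r$ci_high, r$auc)
  # identical seed, identical CI
  r2 <- roc_auc(s, lab, "case", n_boot = 500, seed = 7)
  expect_identical(c(r$ci_low, r$ci_high), c(r2$ci_low, r2$ci_high))
  # oriented for features where LOW values mark the positive class
  rlow <- roc_auc(-s, lab, "case", direction = "lower", n_boot = 0)
  expect_equal(rlow$auc, r$auc)
  expect_error(roc_auc(s, rep("case", 35), "case"), "both classes")
})

test_that("bootstrap CI covers a known AUC at near-nominal rate", {
  # generative model with known theoretical AUC ~0.90 at n = 36 (23 vs 13)
  set.seed(55)
  delta <- sqrt(2) * stats::qnorm(0.90)
  cover <- replicate(120, {
    s <- c(stats::rnorm(23, delta), stats::rnorm(13))
    r <- roc_auc(s, rep(c(1, 0), c(23, 13)), 1, n_boot = 300)
    r$ci_low <= 0.90 && r$ci_high >= 0.90
  })
  expect_gte(mean(cover), 0.85)
})

test_that("median split sends values at the cut to the high group", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4, 5))),
               c("low", "low", "high", "high", "high"))
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_true(all(median_split(rep(7, 4)) == "high"))
  expect_error(median_split(3), "at least 2")
})

test_that("summaries report interpolated median and quartiles", {
  s <- summarize_values(1:9)
  expect_equal(c(s$q1, s$median, s$q3), c(3, 5, 7))
  s1 <- summarize_values(42)
  expect_equal(c(s1$q1, s1$median, s1$q3), c(42, 42, 42))
  expect_equal(summarize_values(c(1, 2, 100))$median, 2)
  expect_error(summarize_values(numeric(0)), "empty")
})
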