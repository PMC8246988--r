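test_that("Yates chi-squared reproduces published cohort comparisons", {
  # sex, controls vs left-TLE: 16/12 vs 17/16
  expect_lt(abs(yates_chi2(rbind(c(16, 12), c(17, 16)))$p_value - 0.856),
            1e-3)
  # surgery outcome, left vs right: 18/15 vs 15/18 (computed 0.6225)
  expect_lt(abs(yates_chi2(rbind(c(18, 15), c(15, 18)))$p_value - 0.623),
            1e-3)
  # perfectly balanced table
  bal <- yates_chi2(rbind(c(10, 10), c(10, 10)))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
})

test_that("Yates chi-squared is invariant to transposition and swaps", {
  tab <- rbind(c(7, 13), c(16, 4))
  p0 <- yates_chi2(tab)$p_value
  expect_equal(yates_chi2(t(tab))$p_value, p0)
  expect_equal(yates_chi2(tab[2:1, ])$p_value, p0)
  expect_equal(yates_chi2(tab[, 2:1])$p_value, p0)
  expect_s3_class(tryCatch(yates_chi2(rbind(c(0, 0), c(3, 4))),
                           error = identity), "tractnorm_zero_marginal")
})

test_that("the two-sample t-test matches hand formulas", {
  x <- c(1.2, 0.8, 1.5, 1.1, 0.9)
  y <- c(0.7, 0.6, 1.0, 0.8, 0.4)
  n <- 5
  sp2 <- ((n - 1) * var(x) + (n - 1) * var(y)) / (2 * n - 2)
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / n))
  res <- two_sample_t(x, y)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 8)

  # identical groups: t = 0, two-tailed p = 1
  same <- two_sample_t(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # one-tailed p is half the two-tailed p when the sign agrees
  p2 <- two_sample_t(x, y, tails = "two")$p_value
  p1 <- two_sample_t(x, y, tails = "one", direction = "greater")$p_value
  expect_equal(p1, p2 / 2, tolerance = 1e-12)
  expect_s3_class(tryCatch(two_sample_t(rep(1, 3), rep(1, 4)),
                           error = identity), "tractnorm_zero_variance")
})

test_that("the Lilliefors statistic matches a direct sup-distance oracle", {
  x <- c(0.2, 1.4, -0.8, 2.1, 0.05, -1.3)
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  d_oracle <- 0
  for (i in seq_len(n)) {
    d_oracle <- max(d_oracle, i / n - pnorm(z[i]), pnorm(z[i]) - (i - 1) / n)
  }
  res <- lilliefors(x, n_sim = 500, seed = 1)
  expect_equal(res$statistic, d_oracle, tolerance = 1e-12)

  # outlier sensitivity: adding a 10-SD point increases the statistic
  set.seed(31)
  base <- rnorm(25)
  with_out <- c(base, 10 * sd(base))
  expect_gt(lilliefors(with_out, n_sim = 200, seed = 1)$statistic,
            lilliefors(base, n_sim = 200, seed = 1)$statistic)

  # statistic agrees with the conventional implementation
  if (requireNamespace("nortest", quietly = TRUE)) {
    set.seed(8)
    y <- rnorm(40)
    expect_equal(lilliefors(y, n_sim = 100, seed = 1)$statistic,
                 unname(nortest::lillie.test(y)$statistic),
                 tolerance = 1e-10)
  }

  # Monte-Carlo p is reproducible bit for bit under a fixed seed
  expect_identical(lilliefors(x, n_sim = 2000, seed = 9)$p_value,
                   lilliefors(x, n_sim = 2000, seed = 9)$p_value)
  expect_s3_class(tryCatch(lilliefors(rep(1, 6)), error = identity),
                  "tractnorm_zero_variance")
})

test_that("the Lilliefors test holds its nominal size on normal samples", {
  n_reject <- 0
  n_rep <- 400
  set.seed(77)
  for (i in seq_len(n_rep)) {
    x <- rnorm(28)
    if (lilliefors(x, n_sim = 400, seed = i)$p_value < 0.05) {
      n_reject <- n_reject + 1
    }
  }
  rate <- n_reject / n_rep
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.08)
})

test_that("Mardia statistics match the double-sum definition", {
  X <- matrix(c(0.1, 0.9, 0.3, 0.7, 0.5,
                0.2, 0.4, 0.8, 0.6, 0.15), 5, 2)
  n <- nrow(X)
  p <- ncol(X)
  A <- sweep(X, 2, colMeans(X))
  S <- t(A) %*% A / n
  Sinv <- solve(S)
  b1 <- 0
  for (i in 1:n) for (j in 1:n) {
    b1 <- b1 + (t(A[i, ]) %*% Sinv %*% A[j, ])^3
  }
  b1 <- b1 / n^2
  b2 <- mean(sapply(1:n, function(i) (t(A[i, ]) %*% Sinv %*% A[i, ])^2))

  res <- mardia(X)
  expect_equal(res$statistic[1], n * as.numeric(b1) / 6, tolerance = 1e-10)
  expect_equal(res$statistic[2], (b2 - p * (p + 2)) /
                 sqrt(8 * p * (p + 2) / n), tolerance = 1e-10)
  expect_equal(res$df[1], p * (p + 1) * (p + 2) / 6)
})

test_that("Mardia reduces to univariate moments and is affine invariant", {
  set.seed(41)
  x <- rnorm(30)^2 # skewed
  res <- mardia(matrix(x))
  m <- mean(x)
  s2 <- mean((x - m)^2)
  skew <- mean((x - m)^3) / s2^1.5
  kurt <- mean((x - m)^4) / s2^2
  expect_equal(res$statistic[1], 30 * skew^2 / 6, tolerance = 1e-10)
  expect_equal(res$statistic[2], (kurt - 3) / sqrt(24 / 30),
               tolerance = 1e-10)

  X <- matrix(rnorm(40 * 3), 40, 3)
  M <- matrix(c(1, 0.2, 0, 0.5, 2, 0.1, 0, 0.3, 1.5), 3, 3)
  Xa <- sweep(X %*% M, 2, c(3, -1, 2), "+")
  expect_lt(max(abs(mardia(X)$statistic - mardia(Xa)$statistic)), 1e-8)
})

test_that("cohort summary tests cover the demographic comparisons", {
  coh <- generate_cohort(generator_config(), seed = 3)
  tests <- cohort_summary_tests(coh$subjects)
  expect_setequal(unique(tests$test_name),
                  c("sex_chi2", "age_t", "onset_age_t", "duration_t",
                    "outcome_chi2", "hs_chi2"))
  expect_true(all(tests$p_value >= 0 & tests$p_value <= 1))
  # same generating distributions for age across groups: rarely significant
  expect_gt(min(tests$p_value[tests$test_name == "age_t"]), 0.001)
})

test_that("normality checks pass on Gaussian-generated control residuals", {
  coh <- generate_cohort(null_config(), seed = 13)
  res <- residualize(coh$fa, coh$subjects)
  checks <- normality_checks(res, coh$subjects, n_sim = 400, seed = 2)
  expect_equal(sum(checks$test_name == "lilliefors_mc"), 10)
  expect_equal(sum(grepl("mardia", checks$test_name)), 4)
  # Gaussian generator: no Bonferroni-corrected rejection expected
  expect_false(any(checks$significant_corrected))
})

test_that("outcome comparisons detect a contralateral deficit in poor outcomes", {
  n_sig <- 0
  for (s in 1:10) {
    coh <- generate_cohort(null_config(), seed = s + 600)
    # impose an extra contralateral deficit on non-seizure-free patients
    worse <- coh$subjects$ilae_outcome %in% "ILAE2plus"
    for (g in c("left_tle", "right_tle")) {
      rows <- worse & coh$subjects$group == g
      contra <- hemisphere_map(g)$contralateral_tracts
      coh$fa[rows, contra] <- coh$fa[rows, contra] - 0.03
    }
    ds <- quick_distance_set(coh, n_reps = 150, seed = s)
    res <- outcome_comparison(ds)
    if (any(res$significant_corrected[res$measure_id == "md_contra"])) {
      n_sig <- n_sig + 1
    }
  }
  expect_gte(n_sig, 8) # >= 80% of replicates at this effect size
})

test_that("shuffled outcome labels control the false-positive rate", {
  coh <- generate_cohort(null_config(), seed = 19)
  ds <- quick_distance_set(coh, n_reps = 150, seed = 5)
  n_shuffle <- 200
  n_sig <- 0
  n_tests <- 0
  set.seed(99)
  for (i in seq_len(n_shuffle)) {
    shuffled <- ds
    pat <- shuffled$group != "control"
    shuffled$ilae_outcome[pat] <- sample(shuffled$ilae_outcome[pat])
    res <- outcome_comparison(shuffled)
    n_sig <- n_sig + sum(res$significant_corrected)
    n_tests <- n_tests + nrow(res)
  }
  # per-test corrected rate: at most alpha/h on average (Bonferroni level)
  expect_lt(n_sig / n_tests, 0.05)
})

test_that("single-class outcomes are a hard error", {
  coh <- generate_cohort(null_config(), seed = 25)
  coh$subjects$ilae_outcome[coh$subjects$group != "control"] <- "ILAE1"
  ds <- quick_distance_set(coh, n_reps = 100, seed = 1)
  ds$ilae_outcome[ds$group != "control"] <- "ILAE1"
  expect_s3_class(tryCatch(outcome_comparison(ds), error = identity),
                  "tractnorm_bad_value")
})
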