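# Auxiliary hypothesis tests: demographics comparisons, surgical-outcome
# tests, and the normality checks gating the Mahalanobis analysis.

test_result <- function(test_name, statistic, df, p_value, tails,
                        direction = NA_character_, h = NA_integer_,
                        significant_corrected = NA) {
  data.frame(test_name = test_name, statistic = statistic, df = df,
             p_value = p_value, tails = tails, direction = direction,
             h = h, significant_corrected = significant_corrected,
             stringsAsFactors = FALSE)
}

#' Yates-corrected chi-squared test on a 2x2 table
#'
#' Pearson chi-squared with continuity correction (|O - E| reduced by 0.5,
#' floored at 0), 1 degree of freedom, two-tailed.
#'
#' @param table 2x2 matrix of non-negative integer counts with all row and
#'   column sums positive.
#' @return one-row test-result data frame.
#' @export
yates_chi2 <- function(table) {
  table <- as.matrix(table)
  tn_assert(all(dim(table) == 2) && all(table >= 0), "bad_value",
            "table must be 2x2 with non-negative counts")
  tn_assert(all(rowSums(table) > 0) && all(colSums(table) > 0),
            "zero_marginal", "all row and column sums must be positive")
  ct <- suppressWarnings(chisq.test(table, correct = TRUE))
  test_result("yates_chi2", unname(ct$statistic), unname(ct$parameter),
              ct$p.value, "two")
}

#' Two-sample t-test
#'
#' Pooled-variance by default (Welch available). For one-tailed tests,
#' `direction` states the hypothesised sign of `mean(x) - mean(y)`.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param tails `"two"` or `"one"`.
#' @param direction for one-tailed tests: `"greater"` or `"less"`.
#' @param variance `"pooled"` (default) or `"welch"`.
#' @return one-row test-result data frame.
#' @export
two_sample_t <- function(x, y, tails = c("two", "one"),
                         direction = c("greater", "less"),
                         variance = c("pooled", "welch")) {
  tails <- match.arg(tails)
  direction <- match.arg(direction)
  variance <- match.arg(variance)
  tn_assert(length(x) >= 2 && length(y) >= 2, "bad_value",
            "each sample needs at least 2 values")
  if (variance == "pooled") {
    tn_assert(stats::var(x) + stats::var(y) > 0, "zero_variance",
              "zero pooled variance")
  }
  alt <- if (tails == "two") "two.sided" else direction
  tt <- t.test(x, y, alternative = alt, var.equal = variance == "pooled")
  test_result("two_sample_t", unname(tt$statistic), unname(tt$parameter),
              tt$p.value, tails,
              direction = if (tails == "one") direction else NA_character_)
}

#' Lilliefors normality test with Monte-Carlo p-value
#'
#' Kolmogorov-Smirnov distance between the empirical CDF and the normal
#' CDF with estimated mean and SD. Because the parameters are estimated,
#' the p-value is computed by seeded Monte-Carlo simulation of the
#' estimated-parameter null (default 10,000 standard-normal samples of the
#' same size), not from the standard KS table.
#'
#' @param x numeric vector, n >= 5, nonzero variance.
#' @param n_sim number of null simulations.
#' @param seed integer seed (bit-reproducible p).
#' @return one-row test-result data frame (`df` = n).
#' @export
lilliefors <- function(x, n_sim = 10000, seed = 1) {
  n <- length(x)
  tn_assert(n >= 5, "bad_value", "need at least 5 observations")
  tn_assert(sd(x) > 0, "zero_variance", "x has zero variance")
  d_obs <- lilliefors_statistic(x)
  d_null <- with_seed(seed, {
    sims <- matrix(rnorm(n * n_sim), n, n_sim)
    apply(sims, 2, lilliefors_statistic)
  })
  p <- mean(d_null >= d_obs)
  test_result("lilliefors_mc", d_obs, n, p, "two")
}

# Sup distance of the ECDF from Phi((x - mean)/sd), evaluated at the two
# one-sided sup points of each order statistic.
lilliefors_statistic <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  phi <- pnorm(z)
  max(seq_len(n) / n - phi, phi - (seq_len(n) - 1) / n)
}

#' Mardia's multivariate skewness and kurtosis tests
#'
#' Double-sum statistics with the maximum-likelihood (1/n) sample
#' covariance: skewness `b1p` tested as `n * b1p / 6` against chi-squared
#' with `p(p+1)(p+2)/6` df; kurtosis `b2p` against its normal
#' approximation around `p(p+2)` (two-tailed).
#'
#' @param X n x p numeric matrix, `n > p + 1`, non-singular covariance.
#' @return two-row test-result data frame (skewness, kurtosis).
#' @export
mardia <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  tn_assert(n > p + 1, "bad_value", "need n > p + 1 observations")
  A <- sweep(X, 2, colMeans(X))
  S <- crossprod(A) / n
  Sinv <- tryCatch(solve(S), error = function(e)
    tn_error("not_spd", "sample covariance is singular"))
  G <- A %*% Sinv %*% t(A)
  b1 <- mean(G^3)
  b2 <- mean(diag(G)^2)
  skew_stat <- n * b1 / 6
  skew_df <- p * (p + 1) * (p + 2) / 6
  skew_p <- pchisq(skew_stat, skew_df, lower.tail = FALSE)
  kurt_stat <- (b2 - p * (p + 2)) / sqrt(8 * p * (p + 2) / n)
  kurt_p <- 2 * pnorm(-abs(kurt_stat))
  rbind(test_result("mardia_skewness", skew_stat, skew_df, skew_p, "two"),
        test_result("mardia_kurtosis", kurt_stat, NA_real_, kurt_p, "two"))
}

#' Demographic comparison tests across groups
#'
#' The cohort-table analogue: pairwise Yates chi-squared tests on sex,
#' surgical outcome and hippocampal sclerosis, and pairwise two-tailed
#' t-tests on age, onset age and epilepsy duration.
#'
#' @param subjects demographics data frame.
#' @param variance t-test variance assumption.
#' @return data frame of test results with a `comparison` column.
#' @export
cohort_summary_tests <- function(subjects, variance = "pooled") {
  grp <- split(subjects, subjects$group)
  pairs <- list(c("control", "left_tle"), c("control", "right_tle"),
                c("left_tle", "right_tle"))
  rows <- list()
  add <- function(label, comparison, row) {
    row$test_name <- label
    row$comparison <- comparison
    rows[[length(rows) + 1]] <<- row
  }
  for (pr in pairs) {
    a <- grp[[pr[1]]]; b <- grp[[pr[2]]]
    if (is.null(a) || is.null(b)) next
    cmp <- paste(pr, collapse = "_vs_")
    tab <- rbind(c(sum(a$sex == "F"), sum(a$sex == "M")),
                 c(sum(b$sex == "F"), sum(b$sex == "M")))
    add("sex_chi2", cmp, yates_chi2(tab))
    add("age_t", cmp, two_sample_t(a$age_years, b$age_years,
                                   variance = variance))
  }
  pat <- pairs[[3]]
  a <- grp[[pat[1]]]; b <- grp[[pat[2]]]
  if (!is.null(a) && !is.null(b)) {
    cmp <- "left_tle_vs_right_tle"
    add("onset_age_t", cmp,
        two_sample_t(a$onset_age_years, b$onset_age_years,
                     variance = variance))
    add("duration_t", cmp,
        two_sample_t(a$duration_years, b$duration_years,
                     variance = variance))
    if (!anyNA(c(a$ilae_outcome, b$ilae_outcome))) {
      tab <- rbind(table(factor(a$ilae_outcome,
                                c("ILAE1", "ILAE2plus"))),
                   table(factor(b$ilae_outcome,
                                c("ILAE1", "ILAE2plus"))))
      add("outcome_chi2", cmp, yates_chi2(tab))
    }
    if (!anyNA(c(a$hs_present, b$hs_present))) {
      tab <- rbind(c(sum(a$hs_present), sum(!a$hs_present)),
                   c(sum(b$hs_present), sum(!b$hs_present)))
      add("hs_chi2", cmp, yates_chi2(tab))
    }
  }
  do.call(rbind, rows)
}

#' Normality checks of the control residual distribution
#'
#' Gating checks for the Mahalanobis analysis: a Lilliefors test per tract
#' on the control FAr values and a Mardia test per hemisphere tract set,
#' with Bonferroni-corrected significance flags.
#'
#' @param residuals FAr matrix from [residualize()].
#' @param subjects demographics data frame aligned with `residuals`.
#' @param alpha significance level.
#' @param n_sim,seed Monte-Carlo controls for [lilliefors()].
#' @return data frame of test results with `measure_id` and Bonferroni
#'   flags (h = 10 univariate, h = 2 multivariate).
#' @export
normality_checks <- function(residuals, subjects, alpha = 0.05,
                             n_sim = 10000, seed = 1) {
  ctrl <- as.matrix(residuals)[subjects$group == "control", , drop = FALSE]
  rows <- list()
  for (tr in tract_names()) {
    row <- lilliefors(ctrl[, tr], n_sim = n_sim,
                      seed = derive_seed(seed, "lilliefors", tr))
    row$measure_id <- tr
    row$h <- 10L
    row$significant_corrected <- row$p_value < alpha / 10
    rows[[length(rows) + 1]] <- row
  }
  for (side in c("left", "right")) {
    cols <- paste0(tract_families(), ".", toupper(substr(side, 1, 1)))
    row <- mardia(ctrl[, cols])
    row$measure_id <- paste0("hemisphere_", side)
    row$h <- 2L
    row$significant_corrected <- row$p_value < alpha / 2
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

#' Surgical-outcome comparisons
#'
#' Per patient group, one-tailed two-sample t-tests of seizure-free
#' (ILAE 1) against not seizure-free (ILAE 2+) patients: each of the ten
#' relabelled z-scores (hypothesis: non-seizure-free more negative, so
#' ILAE1 greater; h = 10) and the log ipsi-/contralateral Mahalanobis
#' distances (hypothesis: non-seizure-free larger, so ILAE1 less; h = 2),
#' with Bonferroni flags.
#'
#' @param distance_set result of [compute_distance_set()].
#' @param alpha significance level.
#' @param variance t-test variance assumption.
#' @return data frame of test results with `measure_id` and `group`.
#' @export
outcome_comparison <- function(distance_set, alpha = 0.05,
                               variance = "pooled") {
  rows <- list()
  for (g in c("left_tle", "right_tle")) {
    d <- distance_set[distance_set$group == g &
                        !is.na(distance_set$ilae_outcome), ]
    sf <- d[d$ilae_outcome == "ILAE1", ]
    nsf <- d[d$ilae_outcome == "ILAE2plus", ]
    tn_assert(nrow(sf) >= 2 && nrow(nsf) >= 2, "bad_value",
              paste("both outcome classes need >= 2 patients in group", g))
    zcols <- relabelled_z_columns(g)
    for (m in names(zcols)) {
      row <- two_sample_t(sf[[zcols[m]]], nsf[[zcols[m]]], tails = "one",
                          direction = "greater", variance = variance)
      row$measure_id <- m
      row$group <- g
      row$h <- 10L
      row$significant_corrected <- row$p_value < alpha / 10
      rows[[length(rows) + 1]] <- row
    }
    for (m in c("md_ipsi", "md_contra")) {
      row <- two_sample_t(log(sf[[m]]), log(nsf[[m]]), tails = "one",
                          direction = "less", variance = variance)
      row$measure_id <- m
      row$group <- g
      row$h <- 2L
      row$significant_corrected <- row$p_value < alpha / 2
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
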