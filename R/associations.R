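# Spearman associations with epilepsy duration: one-tailed t-approximation
# p-values, Bonferroni correction, critical-rho thresholds.

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (ties receive the mean rank).
#'
#' @param x,y numeric vectors of equal length, n >= 4, finite, non-constant.
#' @return scalar rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  tn_assert(length(x) == length(y) && length(x) >= 4, "bad_value",
            "x and y must have equal length >= 4")
  tn_assert(all(is.finite(x)) && all(is.finite(y)), "bad_value",
            "x and y must be finite")
  tn_assert(stats::var(x) > 0 && stats::var(y) > 0, "zero_variance",
            "Spearman correlation undefined for constant input")
  stats::cor(rank(x), rank(y))
}

#' One-tailed p-value for a Spearman correlation
#'
#' Student-t approximation: `t = rho * sqrt(n - 2) / sqrt(1 - rho^2)` with
#' n - 2 degrees of freedom; the p-value is the tail probability in the
#' hypothesised direction, so a correlation opposing the hypothesis gives
#' p > 0.5.
#'
#' @param rho observed correlation, `|rho| <= 1`.
#' @param n sample size, >= 4.
#' @param direction hypothesised sign, `"negative"` or `"positive"`.
#' @return p-value in `[0, 1]`.
#' @export
#' @examples
#' one_tailed_p(-0.493, 33, "negative") # ~0.002
one_tailed_p <- function(rho, n, direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  tn_assert(n >= 4, "bad_value", "n must be >= 4")
  tn_assert(abs(rho) <= 1, "bad_value", "|rho| must be <= 1")
  if (abs(rho) == 1) {
    message("|rho| = 1: t statistic infinite, p = 0 or 1 exactly")
    agrees <- (rho < 0) == (direction == "negative")
    return(if (agrees) 0 else 1)
  }
  t_stat <- rho * sqrt(n - 2) / sqrt(1 - rho^2)
  if (direction == "negative") {
    pt(t_stat, df = n - 2)
  } else {
    pt(t_stat, df = n - 2, lower.tail = FALSE)
  }
}

#' Critical Spearman correlation for a one-tailed Bonferroni test
#'
#' Inverts the t-approximation at the `alpha / h` quantile:
#' `rho* = t* / sqrt(n - 2 + t*^2)`, signed per the hypothesised direction.
#'
#' @param n sample size, >= 4.
#' @param alpha significance level (default 0.05).
#' @param h number of comparisons for the Bonferroni correction.
#' @param direction hypothesised sign.
#' @return the signed critical rho.
#' @export
#' @examples
#' critical_rho(33, 0.05, 10, "negative") # ~ -0.44
critical_rho <- function(n, alpha = 0.05, h = 1,
                         direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  tn_assert(n >= 4, "bad_value", "n must be >= 4")
  tn_assert(alpha / h > 0 && alpha / h < 0.5, "bad_value",
            "alpha / h must be in (0, 0.5)")
  t_star <- qt(1 - alpha / h, df = n - 2)
  rho_star <- t_star / sqrt(n - 2 + t_star^2)
  if (direction == "negative") -rho_star else rho_star
}

association_row <- function(measure_id, group, values, durations,
                            direction, h, alpha) {
  n <- length(values)
  rho <- spearman_rho(values, durations)
  p <- one_tailed_p(rho, n, direction)
  t_stat <- if (abs(rho) < 1) rho * sqrt(n - 2) / sqrt(1 - rho^2) else
    sign(rho) * Inf
  sign_ok <- (rho < 0) == (direction == "negative")
  data.frame(measure_id = measure_id, group = group, rho = rho, n = n,
             t_stat = t_stat, p_one_tailed = p, direction = direction,
             h = h, alpha = alpha,
             significant_bonferroni = (p < alpha / h) && sign_ok,
             stringsAsFactors = FALSE)
}

# Relabelled univariate z column names for a patient group:
# family.ipsi / family.contra -> the z.<tract> column to read.
relabelled_z_columns <- function(group) {
  hm <- hemisphere_map(group)
  c(setNames(paste0("z.", hm$ipsilateral_tracts),
             paste0(tract_families(), ".ipsi")),
    setNames(paste0("z.", hm$contralateral_tracts),
             paste0(tract_families(), ".contra")))
}

#' Associations between distances and epilepsy duration
#'
#' One-tailed Spearman correlations with Bonferroni correction. Univariate
#' z-scores are hypothesised negative with duration (h = 10); Mahalanobis
#' distances positive (h = 2). `scope = "per_group"` analyses left- and
#' right-TLE separately (12 results each, univariate measures relabelled
#' ipsi/contra); `scope = "combined"` pools all patients on `md_ipsi` and
#' `md_contra` only (2 results).
#'
#' @param distance_set result of [compute_distance_set()].
#' @param scope `"per_group"` or `"combined"`.
#' @param alpha significance level.
#' @return data frame of association results.
#' @export
duration_associations <- function(distance_set,
                                  scope = c("per_group", "combined"),
                                  alpha = 0.05) {
  scope <- match.arg(scope)
  pat <- distance_set[distance_set$group != "control" &
                        !is.na(distance_set$duration_years), ]
  rows <- list()
  if (scope == "per_group") {
    for (g in c("left_tle", "right_tle")) {
      d <- pat[pat$group == g, ]
      tn_assert(nrow(d) >= 4, "bad_value",
                paste("fewer than 4 patients with duration in group", g))
      zcols <- relabelled_z_columns(g)
      for (m in names(zcols)) {
        rows[[length(rows) + 1]] <- association_row(
          m, g, d[[zcols[m]]], d$duration_years, "negative", 10, alpha)
      }
      for (m in c("md_ipsi", "md_contra")) {
        rows[[length(rows) + 1]] <- association_row(
          m, g, d[[m]], d$duration_years, "positive", 2, alpha)
      }
    }
  } else {
    tn_assert(nrow(pat) >= 4, "bad_value", "fewer than 4 patients")
    for (m in c("md_ipsi", "md_contra")) {
      rows[[length(rows) + 1]] <- association_row(
        m, "combined", pat[[m]], pat$duration_years, "positive", 2, alpha)
    }
  }
  do.call(rbind, rows)
}
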