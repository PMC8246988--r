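# Subsample-consistency robustness: how often a duration association stays
# Bonferroni-significant when the patient sample is randomly subsampled.

#' Consistency of a duration association under patient subsampling
#'
#' Repeatedly subsamples `m` patients without replacement, recomputes the
#' one-tailed Spearman test at the Bonferroni-corrected level (with n = m
#' in the t-approximation), and reports kappa = the percentage of
#' subsamples yielding a significant correlation in the hypothesised
#' direction. Values near 0% or 100% indicate a robust (non)effect.
#'
#' @param values per-patient measure (z-score or Mahalanobis distance).
#' @param durations per-patient epilepsy durations.
#' @param m subsample size, `5 <= m < length(values)`.
#' @param n_reps number of subsamples.
#' @param alpha,h significance level and Bonferroni comparisons.
#' @param direction hypothesised correlation sign.
#' @param seed integer seed.
#' @return one-row data frame with `kappa` (percent of all `n_reps`),
#'   `n_discarded` (constant-value subsamples dropped), and the settings.
#' @export
consistency <- function(values, durations, m = 30, n_reps = 1000,
                        alpha = 0.05, h = 1,
                        direction = c("negative", "positive"), seed = 1) {
  direction <- match.arg(direction)
  n <- length(values)
  tn_assert(length(durations) == n, "bad_value",
            "values and durations must have equal length")
  tn_assert(m >= 4 && n > m, "bad_value",
            "need 4 <= m < number of patients")
  rho_crit <- critical_rho(m, alpha, h, direction)
  n_sig <- 0L
  n_disc <- 0L
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(n, m)
      x <- values[idx]
      y <- durations[idx]
      if (var(x) == 0 || var(y) == 0) {
        n_disc <- n_disc + 1L
        next
      }
      rho <- stats::cor(rank(x), rank(y))
      sig <- if (direction == "negative") rho < rho_crit else rho > rho_crit
      if (sig) n_sig <- n_sig + 1L
    }
  })
  if (n_disc > 0) {
    message(sprintf("consistency: discarded %d constant subsample(s)",
                    n_disc))
  }
  data.frame(m = m, n_reps = n_reps, kappa = 100 * n_sig / n_reps,
             n_discarded = n_disc, alpha = alpha, h = h,
             direction = direction, seed = seed, stringsAsFactors = FALSE)
}

#' Consistency over a range of subsample sizes
#'
#' One [consistency()] result per subsample size. The significance
#' threshold depends only on m, alpha and h, so kappa typically declines
#' as m decreases.
#'
#' @param values,durations,n_reps,alpha,h,direction,seed see
#'   [consistency()].
#' @param m_range integer vector of subsample sizes (default 20:30).
#' @return data frame with one row per m.
#' @export
consistency_sweep <- function(values, durations, m_range = 20:30,
                              n_reps = 1000, alpha = 0.05, h = 1,
                              direction = "negative", seed = 1) {
  tn_assert(max(m_range) < length(values), "bad_value",
            "max(m_range) must be below the number of patients")
  do.call(rbind, lapply(m_range, function(m)
    consistency(values, durations, m = m, n_reps = n_reps, alpha = alpha,
                h = h, direction = direction,
                seed = derive_seed(seed, "sweep", m))))
}

#' Full consistency report for a distance set
#'
#' Per patient group: kappa for each of the ten relabelled univariate
#' z-measures (direction negative, h = 10) and for the ipsi- and
#' contralateral Mahalanobis distances (direction positive, h = 2) -
#' 12 values per group. Distances are not recomputed per subsample; only
#' the patients entering the correlation are subsampled.
#'
#' @param distance_set result of [compute_distance_set()].
#' @param m,n_reps,alpha,seed see [consistency()].
#' @return data frame with `measure_id`, `group` and the
#'   [consistency()] columns.
#' @export
full_consistency_report <- function(distance_set, m = 30, n_reps = 1000,
                                    alpha = 0.05, seed = 1) {
  rows <- list()
  for (g in c("left_tle", "right_tle")) {
    d <- distance_set[distance_set$group == g &
                        !is.na(distance_set$duration_years), ]
    zcols <- relabelled_z_columns(g)
    for (meas in names(zcols)) {
      row <- consistency(d[[zcols[meas]]], d$duration_years, m = m,
                         n_reps = n_reps, alpha = alpha, h = 10,
                         direction = "negative",
                         seed = derive_seed(seed, g, meas))
      row$measure_id <- meas
      row$group <- g
      rows[[length(rows) + 1]] <- row
    }
    for (meas in c("md_ipsi", "md_contra")) {
      row <- consistency(d[[meas]], d$duration_years, m = m,
                         n_reps = n_reps, alpha = alpha, h = 2,
                         direction = "positive",
                         seed = derive_seed(seed, g, meas))
      row$measure_id <- meas
      row$group <- g
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
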