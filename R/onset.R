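# Extrapolation of the multivariate distance to epilepsy onset
# (duration = 0) and comparison with the control distance distribution.

#' Extrapolate the Mahalanobis distance to disease onset
#'
#' Fits a robust (Huber IRLS) linear regression of patient Mahalanobis
#' distances on epilepsy duration; the intercept `beta0` estimates the
#' distance at duration zero (onset). Because Mahalanobis distances are
#' positively skewed, `beta0` and the control distances are natural-log
#' transformed, and a robust z-score of `log(beta0)` against the log
#' control distances is computed with the subsample-median protocol
#' (subsamples of 54 from the 56 control distances by default). The
#' two-tailed p comes from the standard normal (no direction is
#' hypothesised at onset).
#'
#' @param patient_md positive patient distances (ipsi- or contralateral,
#'   all patients pooled), >= 4 values.
#' @param durations epilepsy durations matching `patient_md`, not all equal.
#' @param control_md positive control reference distances (2 per control).
#' @param side label, `"ipsilateral"` or `"contralateral"`.
#' @param n_subsample,n_reps subsample-median protocol (defaults 54, 1000).
#' @param seed integer seed.
#' @param k Huber tuning constant for the regression.
#' @return an `onset_extrapolation`: list with `side`, `beta0`, `beta1`,
#'   `control_log_mean`, `control_log_sd`, `z_intercept`, `p_two_tailed`,
#'   `n_subsample`, `n_reps`, `seed`.
#' @export
extrapolate_onset <- function(patient_md, durations, control_md,
                              side = c("ipsilateral", "contralateral"),
                              n_subsample = 54, n_reps = 1000, seed = 1,
                              k = 1.345) {
  side <- match.arg(side)
  tn_assert(length(patient_md) >= 4, "bad_value",
            "need at least 4 patient distances")
  tn_assert(length(patient_md) == length(durations), "bad_value",
            "patient_md and durations must have equal length")
  tn_assert(all(patient_md > 0) && all(control_md > 0), "bad_value",
            "distances must be positive (log transform)")
  tn_assert(stats::var(durations) > 0, "zero_variance",
            "durations are all equal")
  fit <- huber_irls(cbind(1, durations), patient_md, k = k)
  beta0 <- unname(fit$coefficients[1])
  beta1 <- unname(fit$coefficients[2])
  tn_assert(beta0 > 0, "bad_value",
            "extrapolated distance at onset is non-positive")
  log_ctrl <- log(control_md)
  z <- robust_zscore(log(beta0), log_ctrl, n_subsample = n_subsample,
                     n_reps = n_reps, seed = seed)
  structure(list(side = side, beta0 = beta0, beta1 = beta1,
                 control_log_mean = mean(log_ctrl),
                 control_log_sd = sd(log_ctrl),
                 z_intercept = as.numeric(z),
                 p_two_tailed = 2 * pnorm(-abs(as.numeric(z))),
                 n_subsample = n_subsample, n_reps = n_reps, seed = seed),
            class = "onset_extrapolation")
}

#' Onset extrapolation for both hemispheres of a distance set
#'
#' Pools all patients' ipsi/contra-relabelled distances and runs
#' [extrapolate_onset()] for each side against the pooled control
#' distances.
#'
#' @param distance_set result of [compute_distance_set()].
#' @param n_subsample,n_reps,seed,k passed to [extrapolate_onset()].
#' @return named list with `ipsilateral` and `contralateral` results.
#' @export
onset_analysis <- function(distance_set, n_subsample = 54, n_reps = 1000,
                           seed = 1, k = 1.345) {
  pat <- distance_set[distance_set$group != "control" &
                        !is.na(distance_set$duration_years), ]
  ctrl_md <- control_distances(distance_set)
  out <- list()
  for (side in c("ipsilateral", "contralateral")) {
    md <- if (side == "ipsilateral") pat$md_ipsi else pat$md_contra
    out[[side]] <- extrapolate_onset(md, pat$duration_years, ctrl_md,
                                     side = side, n_subsample = n_subsample,
                                     n_reps = n_reps,
                                     seed = derive_seed(seed, "onset", side),
                                     k = k)
  }
  out
}
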