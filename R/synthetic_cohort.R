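# Synthetic cohort generator: emulates the statistical structure the
# analysis assumes (correlated tract FA, age/sex effects, a negative
# ipsilateral FA-duration trend with per-patient heterogeneity, outliers).

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a 28/33/33 control / left-TLE / right-TLE cohort with
#' tract-mean FA in a physiological range, exchangeable positive inter-tract
#' correlation (0.4 within hemisphere, 0.3 across), a small negative
#' healthy-aging slope, a male FA offset, and a negative linear duration
#' effect that is stronger ipsilaterally and heterogeneous across patients
#' (different tracts hit in different patients).
#'
#' @param n_control,n_left,n_right group sizes.
#' @param tract_mean_fa length-10 vector of baseline tract-mean FA in (0,1),
#'   named per [tract_names()].
#' @param tract_sd length-10 vector of residual FA standard deviations.
#' @param rho_within,rho_across exchangeable inter-tract correlations within
#'   and across hemispheres (used when `correlation` is NULL).
#' @param correlation optional explicit 10x10 correlation matrix.
#' @param age_slope_per_year FA change per year of age (all subjects).
#' @param sex_offset additive FA offset for males.
#' @param duration_slope_ipsi,duration_slope_contra FA change per year of
#'   epilepsy duration, ipsilateral / contralateral to the focus.
#' @param heterogeneity_sd SD of the per-(patient, tract) multiplicative
#'   loading `1 + h` on the duration effect; 0 = homogeneous.
#' @param outlier_fraction probability that a (subject, tract) cell receives
#'   an additive Gaussian shock of SD `outlier_magnitude_sd`.
#' @param outlier_magnitude_sd SD of the outlier shock.
#' @param age_range,duration_range uniform sampling intervals (years); onset
#'   age is `age - duration`, so the duration identity holds by construction.
#' @param sex_female_prob,ilae1_prob,hs_prob per-group probabilities of
#'   female sex, ILAE class 1 outcome, and hippocampal sclerosis.
#' @param rng_seed integer seed used by [generate_cohort()] by default.
#' @return a validated `generator_config` list.
#' @export
generator_config <- function(n_control = 28, n_left = 33, n_right = 33,
                             tract_mean_fa = NULL,
                             tract_sd = rep(0.02, 10),
                             rho_within = 0.4, rho_across = 0.3,
                             correlation = NULL,
                             age_slope_per_year = -4e-4,
                             sex_offset = 0.005,
                             duration_slope_ipsi = -6e-4,
                             duration_slope_contra = -2e-4,
                             heterogeneity_sd = 0.5,
                             outlier_fraction = 0,
                             outlier_magnitude_sd = 0.05,
                             age_range = c(18, 60),
                             duration_range = c(1, 50),
                             sex_female_prob = c(control = 16 / 28,
                                                 left_tle = 17 / 33,
                                                 right_tle = 24 / 33),
                             ilae1_prob = c(left_tle = 18 / 33,
                                            right_tle = 15 / 33),
                             hs_prob = c(left_tle = 28 / 33,
                                         right_tle = 20 / 33),
                             rng_seed = 1L) {
  if (is.null(tract_mean_fa)) {
    base <- c(ATR = 0.42, CG = 0.47, CH = 0.39, F = 0.36, UF = 0.43)
    tract_mean_fa <- setNames(rep(base, each = 2), tract_names())
  }
  if (is.null(correlation)) {
    correlation <- exchangeable_correlation(rho_within, rho_across)
  }
  cfg <- list(n_control = n_control, n_left = n_left, n_right = n_right,
              tract_mean_fa = tract_mean_fa, tract_sd = tract_sd,
              correlation = correlation,
              age_slope_per_year = age_slope_per_year,
              sex_offset = sex_offset,
              duration_slope_ipsi = duration_slope_ipsi,
              duration_slope_contra = duration_slope_contra,
              heterogeneity_sd = heterogeneity_sd,
              outlier_fraction = outlier_fraction,
              outlier_magnitude_sd = outlier_magnitude_sd,
              age_range = age_range, duration_range = duration_range,
              sex_female_prob = sex_female_prob, ilae1_prob = ilae1_prob,
              hs_prob = hs_prob, rng_seed = as.integer(rng_seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

# Exchangeable correlation: rho_w within each hemisphere, rho_a across.
exchangeable_correlation <- function(rho_within, rho_across) {
  tn <- tract_names()
  hemi <- substring(tn, nchar(tn))
  R <- outer(hemi, hemi, function(a, b)
    ifelse(a == b, rho_within, rho_across))
  diag(R) <- 1
  dimnames(R) <- list(tn, tn)
  R
}

validate_generator_config <- function(cfg) {
  tn_assert(all(c(cfg$n_control, cfg$n_left, cfg$n_right) >= 0) &&
              cfg$n_control + cfg$n_left + cfg$n_right > 0,
            "bad_value", "group sizes must be non-negative, not all zero")
  tn_assert(length(cfg$tract_mean_fa) == 10 &&
              all(cfg$tract_mean_fa > 0 & cfg$tract_mean_fa < 1),
            "bad_value", "tract_mean_fa must be 10 values in (0,1)")
  tn_assert(length(cfg$tract_sd) == 10 && all(cfg$tract_sd > 0),
            "bad_value", "tract_sd must be 10 positive values")
  R <- cfg$correlation
  tn_assert(is.matrix(R) && all(dim(R) == 10) &&
              max(abs(R - t(R))) < 1e-10,
            "bad_value", "correlation must be a symmetric 10x10 matrix")
  ev <- tryCatch(chol(R), error = function(e) NULL)
  tn_assert(!is.null(ev), "not_spd",
            "inter-tract correlation matrix is not positive definite")
  tn_assert(cfg$heterogeneity_sd >= 0, "bad_value",
            "heterogeneity_sd must be non-negative")
  tn_assert(cfg$outlier_fraction >= 0 && cfg$outlier_fraction < 1,
            "bad_value", "outlier_fraction must be in [0,1)")
  tn_assert(cfg$outlier_magnitude_sd > 0, "bad_value",
            "outlier_magnitude_sd must be positive")
  invisible(cfg)
}

#' Generate a synthetic cohort
#'
#' Draws demographics and a tract-FA table with the generative model
#' `FA[i, j] = mean[j] + age_slope * age_i + sex_offset * male_i +
#' slope_side(j) * duration_i * (1 + h[i, j]) + correlated noise`,
#' where `slope_side` is the ipsi- or contralateral duration slope for
#' patients (0 for controls) and `h ~ N(0, heterogeneity_sd)` is the
#' per-(patient, tract) loading. Optional outlier shocks are added to
#' randomly chosen cells. Fully reproducible for a fixed seed.
#'
#' Any FA draw falling outside (0,1) is clipped to `[1e-4, 1 - 1e-4]` and
#' reported via a warning giving the number of clipped cells.
#'
#' @param config a [generator_config()].
#' @param seed integer seed; defaults to `config$rng_seed`.
#' @return a cohort list with `subjects` and `fa`, as from [read_cohort()].
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(rng_seed = 7))
#' dim(coh$fa)
generate_cohort <- function(config = generator_config(),
                            seed = config$rng_seed) {
  validate_generator_config(config)
  with_seed(seed, {
    groups <- rep(subject_groups(),
                  c(config$n_control, config$n_left, config$n_right))
    n <- length(groups)
    ids <- sprintf("%s%03d",
                   c("C", "L", "R")[match(groups, subject_groups())],
                   unlist(lapply(c(config$n_control, config$n_left,
                                   config$n_right), seq_len)))
    sex <- ifelse(rbinom(n, 1, config$sex_female_prob[groups]) == 1, "F", "M")
    age <- runif(n, config$age_range[1], config$age_range[2])
    is_pat <- groups != "control"
    duration <- rep(NA_real_, n)
    # duration cannot exceed age; truncate the sampling interval per patient
    dur_hi <- pmin(config$duration_range[2], age - 0.5)
    duration[is_pat] <- runif(sum(is_pat),
                              pmin(config$duration_range[1], dur_hi[is_pat]),
                              dur_hi[is_pat])
    onset <- ifelse(is_pat, age - duration, NA_real_)
    ilae <- rep(NA_character_, n)
    ilae[is_pat] <- ifelse(rbinom(sum(is_pat), 1,
                                  config$ilae1_prob[groups[is_pat]]) == 1,
                           "ILAE1", "ILAE2plus")
    hs <- rep(NA, n)
    hs[is_pat] <- rbinom(sum(is_pat), 1, config$hs_prob[groups[is_pat]]) == 1

    p <- 10L
    Sigma <- diag(config$tract_sd) %*% config$correlation %*%
      diag(config$tract_sd)
    noise <- matrix(rnorm(n * p), n, p) %*% chol(Sigma)
    fa <- matrix(rep(config$tract_mean_fa, each = n), n, p) +
      config$age_slope_per_year * age +
      config$sex_offset * (sex == "M") +
      noise

    # duration effect with per-(patient, tract) heterogeneous loadings
    slope <- matrix(0, n, p)
    for (g in c("left_tle", "right_tle")) {
      rows <- groups == g
      if (!any(rows)) next
      hm <- hemisphere_map(g)
      slope[rows, match(hm$ipsilateral_tracts, tract_names())] <-
        config$duration_slope_ipsi
      slope[rows, match(hm$contralateral_tracts, tract_names())] <-
        config$duration_slope_contra
    }
    loading <- 1 + matrix(rnorm(n * p, 0, config$heterogeneity_sd), n, p)
    dur_mat <- ifelse(is.na(duration), 0, duration)
    fa <- fa + slope * dur_mat * loading

    if (config$outlier_fraction > 0) {
      hit <- matrix(rbinom(n * p, 1, config$outlier_fraction), n, p) == 1
      fa[hit] <- fa[hit] + rnorm(sum(hit), 0, config$outlier_magnitude_sd)
    }

    n_clip <- sum(fa <= 0 | fa >= 1)
    if (n_clip > 0) {
      warning(sprintf("%d FA draw(s) fell outside (0,1) and were clipped",
                      n_clip), call. = FALSE)
      fa <- pmin(pmax(fa, 1e-4), 1 - 1e-4)
    }

    dem <- data.frame(subject_id = ids, group = groups, sex = sex,
                      age_years = round(age, 2),
                      onset_age_years = round(onset, 2),
                      duration_years = round(duration, 2),
                      ilae_outcome = ilae, hs_present = hs,
                      stringsAsFactors = FALSE)
    fa_df <- data.frame(subject_id = ids, fa, check.names = FALSE)
    colnames(fa_df) <- c("subject_id", tract_names())
    as_cohort(dem, fa_df)
  })
}
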