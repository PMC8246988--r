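# Robust removal of sex and healthy-aging effects from tract FA.

# Core Huber IRLS on an explicit design matrix (column one = intercept).
# Scale is re-estimated each iteration as median(|r|)/0.6745; weights are 1
# for |r| <= k * scale and k * scale / |r| beyond.
huber_irls <- function(X, y, k = 1.345, max_iter = 100, tol = 1e-8) {
  tn_assert(nrow(X) >= 4, "bad_value", "need at least 4 observations")
  qx <- qr(X)
  tn_assert(qx$rank == ncol(X), "rank_deficient",
            "design matrix is rank deficient")
  beta <- qr.coef(qx, y)
  w <- rep(1, length(y))
  s <- 0
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    r <- as.vector(y - X %*% beta)
    s <- median(abs(r)) / 0.6745
    # scale below numerical precision: exact fit (or >50% of residuals zero)
    if (s < sqrt(.Machine$double.eps) * max(abs(y), 1)) {
      w <- rep(1, length(y))
      converged <- TRUE
      break
    }
    w <- pmin(1, k * s / abs(r))
    w[abs(r) <= k * s] <- 1
    beta_new <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(coefficients = beta, final_weights = w, scale_estimate = s,
       n_iterations = iter, converged = converged)
}

#' Huber M-estimator fit of FA on age and sex
#'
#' Iteratively reweighted least squares for the Huber criterion with tuning
#' constant `k` (default 1.345, the conventional 95%-efficiency constant).
#' The scale is re-estimated at every iteration from the median absolute
#' deviation of the residuals (consistency factor 1/0.6745); iteration
#' stops when the largest coefficient change falls below `tol` or after
#' `max_iter` iterations (then `converged = FALSE`, no error).
#'
#' @param age_years numeric vector of ages.
#' @param sex character (`"F"`/`"M"`) or 0/1 numeric vector; males coded 1.
#'   If constant, the sex term is dropped with a warning.
#' @param response numeric vector of tract FA values.
#' @param k Huber tuning constant.
#' @param max_iter,tol iteration controls.
#' @return a `huber_fit`: list with `coefficients` (named `intercept`,
#'   `age_slope`, `sex_offset`), `final_weights`, `scale_estimate`,
#'   `n_iterations`, `converged`, `sex_dropped`.
#' @export
huber_irls_fit <- function(age_years, sex, response, k = 1.345,
                           max_iter = 100, tol = 1e-8) {
  sex01 <- if (is.character(sex) || is.factor(sex)) {
    as.numeric(as.character(sex) == "M")
  } else as.numeric(sex)
  tn_assert(length(age_years) == length(response) &&
              length(sex01) == length(response), "bad_value",
            "age, sex and response must have equal length")
  sex_dropped <- length(unique(sex01)) < 2
  if (sex_dropped) {
    warning("sex is constant; dropping the sex term", call. = FALSE)
    X <- cbind(intercept = 1, age_slope = age_years)
  } else {
    X <- cbind(intercept = 1, age_slope = age_years, sex_offset = sex01)
  }
  fit <- huber_irls(X, response, k = k, max_iter = max_iter, tol = tol)
  coefs <- c(intercept = 0, age_slope = 0, sex_offset = 0)
  coefs[colnames(X)] <- fit$coefficients
  structure(list(coefficients = coefs,
                 final_weights = fit$final_weights,
                 scale_estimate = fit$scale_estimate,
                 n_iterations = fit$n_iterations,
                 converged = fit$converged,
                 sex_dropped = sex_dropped),
            class = "huber_fit")
}

predict_huber <- function(fit, age_years, sex01) {
  fit$coefficients["intercept"] +
    fit$coefficients["age_slope"] * age_years +
    fit$coefficients["sex_offset"] * sex01
}

#' Remove sex and healthy-aging effects from every tract
#'
#' Fits one robust linear model per tract (FA ~ age + sex, Huber IRLS) on
#' the chosen fit population and subtracts the fitted covariate effect from
#' every subject's FA, giving the residual table FAr used by all distance
#' computations. Disease duration is never a covariate here.
#'
#' @param fa tract-FA matrix (subjects x 10), rownames = subject ids.
#' @param subjects demographics data frame aligned with `fa`.
#' @param fit_population `"controls_only"` (default; patients' disease
#'   effects must not be absorbed into the aging model) or `"all_subjects"`.
#' @param k,max_iter,tol passed to [huber_irls_fit()].
#' @return a `residual_table`: numeric matrix of FAr with the same shape and
#'   dimnames as `fa`; per-tract fits attached as attribute `"fits"`.
#' @export
residualize <- function(fa, subjects,
                        fit_population = c("controls_only", "all_subjects"),
                        k = 1.345, max_iter = 100, tol = 1e-8) {
  fit_population <- match.arg(fit_population)
  tn_assert(identical(rownames(fa), subjects$subject_id), "id_mismatch",
            "fa rownames must equal subjects$subject_id")
  rows <- if (fit_population == "controls_only") {
    subjects$group == "control"
  } else rep(TRUE, nrow(subjects))
  tn_assert(any(rows), "bad_value", "fit population is empty")
  sex01 <- as.numeric(subjects$sex == "M")
  res <- fa
  fits <- vector("list", ncol(fa))
  names(fits) <- colnames(fa)
  for (tr in colnames(fa)) {
    fit <- huber_irls_fit(subjects$age_years[rows], sex01[rows],
                          fa[rows, tr], k = k, max_iter = max_iter, tol = tol)
    res[, tr] <- fa[, tr] - predict_huber(fit, subjects$age_years, sex01)
    fits[[tr]] <- fit
  }
  structure(res, fits = fits, fit_population = fit_population,
            class = c("residual_table", class(res)))
}
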