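# Normative distances: shrinkage covariance, Mahalanobis distance, robust
# (subsample-median) z-scores and Mahalanobis distances, and the full
# per-subject distance set.

#' Ledoit-Wolf shrinkage covariance
#'
#' Linear shrinkage of the (maximum-likelihood, 1/n) sample covariance
#' toward the scaled identity, with the analytically optimal intensity.
#' The result is always symmetric positive definite, even for constant
#' columns or n close to p, which stabilises the matrix inversion inside
#' the Mahalanobis distance.
#'
#' @param samples n x p numeric matrix (n >= 3 rows).
#' @param estimator `"ledoit_wolf_linear"` (default) or `"sample"` (plain
#'   unbiased sample covariance; no shrinkage, intensity 0).
#' @return a `shrinkage_covariance`: list with `matrix`,
#'   `shrinkage_intensity` and `estimator_name`.
#' @export
shrinkage_covariance <- function(samples,
                                 estimator = c("ledoit_wolf_linear",
                                               "sample")) {
  estimator <- match.arg(estimator)
  samples <- as.matrix(samples)
  tn_assert(nrow(samples) >= 3, "bad_value", "need at least 3 samples")
  if (estimator == "ledoit_wolf_linear") {
    out <- cpp_lw_cov(samples)
    mat <- out$matrix
    rho <- out$shrinkage_intensity
  } else {
    mat <- stats::cov(samples)
    rho <- 0
  }
  dimnames(mat) <- list(colnames(samples), colnames(samples))
  structure(list(matrix = mat, shrinkage_intensity = rho,
                 estimator_name = estimator),
            class = "shrinkage_covariance")
}

#' Mahalanobis distance
#'
#' `sqrt((x - mu)' C^{-1} (x - mu))`, computed through a Cholesky
#' factorisation (never an explicit inverse).
#'
#' @param x,mu numeric p-vectors.
#' @param C p x p covariance matrix or a [shrinkage_covariance()] object.
#' @return non-negative scalar distance.
#' @export
#' @examples
#' mahalanobis_distance(c(1, 1), c(0, 0), matrix(c(1, .5, .5, 1), 2))
mahalanobis_distance <- function(x, mu, C) {
  if (inherits(C, "shrinkage_covariance")) C <- C$matrix
  tn_assert(length(x) == length(mu) && all(dim(C) == length(x)),
            "bad_value", "dimension mismatch between x, mu and C")
  L <- tryCatch(chol(C), error = function(e)
    tn_error("not_spd", "covariance matrix is not positive definite"))
  v <- backsolve(L, x - mu, transpose = TRUE)
  sqrt(sum(v^2))
}

#' Robust (subsample-median) z-score
#'
#' For each of `n_reps` repetitions, draws `n_subsample` reference values
#' without replacement and standardises `value` by the subsample mean and
#' SD (n-1 denominator); the median over repetitions is returned. The
#' median over subsamples damps the influence of outlying reference values.
#'
#' @param value scalar to score.
#' @param reference numeric vector, longer than `n_subsample`, with nonzero
#'   variance.
#' @param n_subsample subsample size (default 24).
#' @param n_reps number of subsamples (default 1000).
#' @param seed integer seed (deterministic output).
#' @return scalar median z; attribute `"n_discarded"` counts zero-variance
#'   subsamples that were dropped (all dropped is an error).
#' @export
robust_zscore <- function(value, reference, n_subsample = 24,
                          n_reps = 1000, seed = 1) {
  reference <- as.numeric(reference)
  tn_assert(length(reference) > n_subsample, "bad_value",
            "reference must be longer than n_subsample")
  tn_assert(stats::var(reference) > 0, "zero_variance",
            "reference has zero variance")
  out <- cpp_robust_z(value, reference, as.integer(n_subsample),
                      as.integer(n_reps), as.integer(seed))
  tn_assert(is.finite(out$value), "zero_variance",
            "all subsamples had zero variance")
  if (out$n_discarded > 0) {
    message(sprintf("robust_zscore: discarded %d zero-variance subsample(s)",
                    out$n_discarded))
  }
  structure(out$value, n_discarded = out$n_discarded)
}

#' Robust (subsample-median) Mahalanobis distance
#'
#' For each repetition, subsamples `n_subsample` reference rows, estimates
#' the subsample mean and shrinkage covariance, and evaluates the
#' Mahalanobis distance of `x`; the median over repetitions is returned.
#'
#' @param x numeric p-vector.
#' @param reference m x p matrix, `m > n_subsample >= p + 2`.
#' @param n_subsample,n_reps,seed as in [robust_zscore()].
#' @param estimator covariance estimator, see [shrinkage_covariance()].
#' @return non-negative scalar; attribute `"n_discarded"` as in
#'   [robust_zscore()].
#' @export
robust_mahalanobis <- function(x, reference, n_subsample = 24,
                               n_reps = 1000, seed = 1,
                               estimator = c("ledoit_wolf_linear",
                                             "sample")) {
  estimator <- match.arg(estimator)
  reference <- as.matrix(reference)
  tn_assert(length(x) == ncol(reference), "bad_value",
            "length(x) must equal ncol(reference)")
  tn_assert(nrow(reference) > n_subsample, "bad_value",
            "reference must have more rows than n_subsample")
  tn_assert(n_subsample >= ncol(reference) + 2, "bad_value",
            "n_subsample must be at least p + 2")
  out <- cpp_robust_md(as.numeric(x), reference, as.integer(n_subsample),
                       as.integer(n_reps), as.integer(seed),
                       estimator == "ledoit_wolf_linear")
  tn_assert(is.finite(out$value), "zero_variance",
            "all subsamples gave a singular covariance")
  if (out$n_discarded > 0) {
    message(sprintf(
      "robust_mahalanobis: discarded %d singular subsample(s)",
      out$n_discarded))
  }
  structure(out$value, n_discarded = out$n_discarded)
}

#' Per-subject robust distance set
#'
#' Computes, for every subject, ten robust univariate z-scores (one per
#' tract) and two robust Mahalanobis distances (left- and right-hemisphere
#' tract sets), all relative to the control residual distribution. For a
#' control subject, that subject is removed from the reference before
#' subsampling (leave-one-out); patients use all controls. Patients
#' additionally get `md_ipsi` / `md_contra` via [hemisphere_map()].
#'
#' Random streams are derived per (subject, measure) from the single
#' `seed`, so results do not depend on subject order.
#'
#' @param residuals FAr matrix from [residualize()].
#' @param subjects demographics data frame aligned with `residuals`.
#' @param n_subsample,n_reps,seed,estimator see [robust_mahalanobis()].
#' @return a `distance_set` data frame: one row per subject with the
#'   demographics, `z.<tract>` columns, `md_left`, `md_right`, `md_ipsi`,
#'   `md_contra`; parameters in attribute `"params"`.
#' @export
compute_distance_set <- function(residuals, subjects, n_subsample = 24,
                                 n_reps = 1000, seed = 1,
                                 estimator = c("ledoit_wolf_linear",
                                               "sample")) {
  estimator <- match.arg(estimator)
  tn_assert(identical(rownames(residuals), subjects$subject_id),
            "id_mismatch", "residual rownames must equal subjects$subject_id")
  ctrl_ids <- subjects$subject_id[subjects$group == "control"]
  tn_assert(length(ctrl_ids) >= n_subsample + 2, "too_few_controls",
            sprintf("need at least %d controls for n_subsample = %d",
                    n_subsample + 2, n_subsample))
  res <- as.matrix(residuals)
  hemi_cols <- list(left = paste0(tract_families(), ".L"),
                    right = paste0(tract_families(), ".R"))
  use_lw <- estimator == "ledoit_wolf_linear"

  n <- nrow(subjects)
  z <- matrix(NA_real_, n, length(tract_names()),
              dimnames = list(subjects$subject_id,
                              paste0("z.", tract_names())))
  md <- matrix(NA_real_, n, 2, dimnames = list(subjects$subject_id,
                                               c("md_left", "md_right")))
  for (i in seq_len(n)) {
    id <- subjects$subject_id[i]
    ref_ids <- setdiff(ctrl_ids, id)
    for (tr in tract_names()) {
      out <- cpp_robust_z(res[i, tr], res[ref_ids, tr],
                          as.integer(n_subsample), as.integer(n_reps),
                          derive_seed(seed, id, tr))
      z[i, paste0("z.", tr)] <- out$value
    }
    for (side in c("left", "right")) {
      cols <- hemi_cols[[side]]
      out <- cpp_robust_md(res[i, cols], res[ref_ids, cols, drop = FALSE],
                           as.integer(n_subsample), as.integer(n_reps),
                           derive_seed(seed, id, paste0("md_", side)),
                           use_lw)
      md[i, paste0("md_", side)] <- out$value
    }
  }

  md_ipsi <- ifelse(subjects$group == "left_tle", md[, "md_left"],
                    ifelse(subjects$group == "right_tle", md[, "md_right"],
                           NA_real_))
  md_contra <- ifelse(subjects$group == "left_tle", md[, "md_right"],
                      ifelse(subjects$group == "right_tle", md[, "md_left"],
                             NA_real_))
  ds <- data.frame(subjects, z, md, md_ipsi = md_ipsi,
                   md_contra = md_contra, check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(ds) <- NULL
  structure(ds, params = list(n_subsample = n_subsample, n_reps = n_reps,
                              seed = seed, estimator = estimator),
            class = c("distance_set", class(ds)))
}

#' Pooled control Mahalanobis distances
#'
#' The control reference distribution of hemispheric distances: each
#' control contributes its left- and right-hemisphere distance (2 per
#' control; 56 values for 28 controls).
#'
#' @param distance_set result of [compute_distance_set()].
#' @return numeric vector of control distances.
#' @export
control_distances <- function(distance_set) {
  ctrl <- distance_set[distance_set$group == "control", ]
  c(ctrl$md_left, ctrl$md_right)
}
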