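# Independent re-derivation of the Ledoit-Wolf linear shrinkage intensity,
# written directly from the textbook formulas (1/n covariance, identity
# target scaled by the mean variance).
lw_oracle <- function(X) {
  n <- nrow(X)
  p <- ncol(X)
  A <- sweep(X, 2, colMeans(X))
  S <- t(A) %*% A / n
  m <- sum(diag(S)) / p
  d2 <- sum((S - m * diag(p))^2) / p
  b2bar <- 0
  for (k in seq_len(n)) {
    xk <- A[k, ]
    b2bar <- b2bar + sum((outer(xk, xk) - S)^2)
  }
  b2bar <- b2bar / n^2 / p
  b2 <- min(b2bar, d2)
  list(intensity = b2 / d2, matrix = b2 / d2 * m * diag(p) +
         (1 - b2 / d2) * S)
}

test_that("mahalanobis_distance matches hand-computed cases", {
  expect_equal(mahalanobis_distance(c(1, 2), c(1, 2), diag(2)), 0)
  # univariate reduction: |x - mu| / sigma
  expect_equal(mahalanobis_distance(3, 1, matrix(4)), 1)
  # hand-inverted 2x2: (1,1)' [[1,.5],[.5,1]]^{-1} (1,1) = 4/3
  expect_equal(mahalanobis_distance(c(1, 1), c(0, 0),
                                    matrix(c(1, 0.5, 0.5, 1), 2)),
               sqrt(4 / 3), tolerance = 1e-12)
  expect_s3_class(tryCatch(
    mahalanobis_distance(c(1, 1), c(0, 0), matrix(c(1, 2, 2, 1), 2)),
    error = identity), "tractnorm_not_spd")
})

test_that("mahalanobis distance is affine invariant and scales linearly", {
  set.seed(12)
  ref <- matrix(rnorm(40 * 3), 40, 3)
  x <- rnorm(3)
  d1 <- mahalanobis_distance(x, colMeans(ref), cov(ref))
  # invertible affine map applied jointly to x and the reference
  M <- matrix(c(2, 0.3, 0, 0.1, 1.5, 0.2, 0, 0.4, 0.8), 3, 3)
  b <- c(1, -2, 0.5)
  refm <- sweep(ref %*% t(M), 2, b, "+")
  xm <- as.vector(M %*% x + b)
  d2 <- mahalanobis_distance(xm, colMeans(refm), cov(refm))
  expect_equal(d1, d2, tolerance = 1e-6)

  # scaling (x - mu) by lambda scales the distance by exactly lambda
  mu <- colMeans(ref)
  C <- cov(ref)
  lam <- 3.7
  expect_equal(mahalanobis_distance(mu + lam * (x - mu), mu, C),
               lam * mahalanobis_distance(x, mu, C), tolerance = 1e-12)
})

test_that("shrinkage covariance matches an independent re-derivation", {
  X <- matrix(c(0.1, 0.5, 0.9, 0.3, 0.7, 0.2,
                0.4, 0.8, 0.1, 0.6, 0.2, 0.9,
                0.3, 0.3, 0.5, 0.7, 0.1, 0.8), 6, 3)
  sc <- shrinkage_covariance(X)
  orc <- lw_oracle(X)
  expect_equal(sc$shrinkage_intensity, orc$intensity, tolerance = 1e-10)
  expect_equal(unname(sc$matrix), orc$matrix, tolerance = 1e-10)
})

test_that("shrinkage covariance is consistent at large n and always SPD", {
  set.seed(61)
  truth <- diag(c(4, 2, 1, 0.5, 0.25))
  X <- matrix(rnorm(10000 * 5), 10000, 5) %*% sqrt(truth)
  sc <- shrinkage_covariance(X)
  expect_lt(sc$shrinkage_intensity, 0.05)
  expect_lt(max(abs(sc$matrix - truth) / diag(truth)), 0.05)

  # small-n SPD guarantee, including a constant column
  set.seed(62)
  min_eigs <- replicate(1000, {
    Y <- matrix(rnorm(24 * 5), 24, 5)
    min(eigen(shrinkage_covariance(Y)$matrix, symmetric = TRUE,
              only.values = TRUE)$values)
  })
  expect_true(all(min_eigs > 0))
  Yc <- cbind(matrix(rnorm(24 * 4), 24, 4), 0.5)
  expect_gt(min(eigen(shrinkage_covariance(Yc)$matrix, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  expect_error(shrinkage_covariance(matrix(1:4, 2, 2)))
})

test_that("robust z-scores behave at the centre and track the full sample", {
  set.seed(5)
  ref <- rnorm(28)
  sym <- c(ref, -ref) / sd(c(ref, -ref)) # symmetric, mean 0
  z <- robust_zscore(mean(sym), sym, n_subsample = 24, seed = 9)
  expect_lt(abs(z), 0.05)

  expect_s3_class(tryCatch(robust_zscore(1, rep(2, 30)), error = identity),
                  "tractnorm_zero_variance")

  # large reference: subsample-median z agrees with the plain z
  set.seed(6)
  big <- rnorm(10000, 5, 2)
  v <- 7.3
  z_full <- (v - mean(big)) / sd(big)
  z_rob <- robust_zscore(v, big, n_subsample = 24, n_reps = 2000, seed = 2)
  expect_lt(abs(z_rob - z_full), 0.05)

  # determinism
  expect_identical(robust_zscore(1.1, ref, seed = 33),
                   robust_zscore(1.1, ref, seed = 33))
})

test_that("robust Mahalanobis agrees with |robust z| in one dimension", {
  set.seed(8)
  ref <- matrix(rnorm(28, 0, 1.3), 28, 1)
  for (v in c(-1.5, 0.4, 2.0)) {
    md <- robust_mahalanobis(v, ref, n_subsample = 24, n_reps = 1500,
                             seed = 44)
    z <- robust_zscore(v, ref[, 1], n_subsample = 24, n_reps = 1500,
                       seed = 44)
    expect_lt(abs(md - abs(z)), 0.05)
  }
})

test_that("the centroid has a small robust distance", {
  set.seed(9)
  ref <- matrix(rnorm(28 * 5), 28, 5)
  d_centre <- robust_mahalanobis(colMeans(ref), ref, n_reps = 500, seed = 3)
  d_pop <- vapply(seq_len(nrow(ref)), function(i)
    as.numeric(robust_mahalanobis(ref[i, ], ref[-i, ], n_subsample = 24,
                                  n_reps = 100, seed = 3)), 0)
  expect_lt(d_centre, median(d_pop))
})

test_that("squared distances of fresh MVN draws follow chi-squared", {
  set.seed(10)
  p <- 5
  R <- matrix(0.4, p, p)
  diag(R) <- 1
  L <- chol(R)
  X <- matrix(rnorm(2000 * p), 2000, p) %*% L
  d2 <- apply(X, 1, function(x)
    mahalanobis_distance(x, rep(0, p), R)^2)
  expect_gt(suppressWarnings(ks.test(d2, pchisq, df = p))$p.value, 0.01)
})

test_that("the distance set follows the leave-one-out reference protocol", {
  coh <- generate_cohort(null_config(), seed = 23)
  ds <- quick_distance_set(coh, n_reps = 150, seed = 7)

  # 2 distances per control: 56 for 28 controls
  expect_length(control_distances(ds), 56)
  expect_true(all(control_distances(ds) >= 0))

  # ipsi/contra relabelling follows laterality
  left <- ds$group == "left_tle"
  right <- ds$group == "right_tle"
  expect_identical(ds$md_ipsi[left], ds$md_left[left])
  expect_identical(ds$md_ipsi[right], ds$md_right[right])
  expect_identical(ds$md_contra[left], ds$md_right[left])
  expect_true(all(is.na(ds$md_ipsi[ds$group == "control"])))

  # determinism for identical seed, and independence from subject order
  ds2 <- quick_distance_set(coh, n_reps = 150, seed = 7)
  expect_identical(as.data.frame(ds), as.data.frame(ds2))

  perm <- sample(nrow(coh$subjects))
  coh_perm <- list(subjects = coh$subjects[perm, ],
                   fa = coh$fa[perm, ])
  coh_perm$subjects <- coh_perm$subjects[order(coh_perm$subjects$subject_id), ]
  coh_perm$fa <- coh_perm$fa[order(rownames(coh_perm$fa)), ]
  rownames(coh_perm$subjects) <- NULL
  ds3 <- quick_distance_set(coh_perm, n_reps = 150, seed = 7)
  expect_equal(as.data.frame(ds), as.data.frame(ds3))

  expect_s3_class(tryCatch(
    compute_distance_set(residualize(coh$fa, coh$subjects),
                         coh$subjects, n_subsample = 27),
    error = identity), "tractnorm_too_few_controls")
})

test_that("null cohorts give indistinguishable patient and control distances", {
  n_ok <- 0
  for (s in 1:20) {
    coh <- generate_cohort(null_config(), seed = s + 100)
    ds <- quick_distance_set(coh, n_reps = 100, seed = s)
    pat_md <- c(ds$md_left[ds$group != "control"],
                ds$md_right[ds$group != "control"])
    p <- wilcox.test(pat_md, control_distances(ds))$p.value
    if (p > 0.01) n_ok <- n_ok + 1
  }
  expect_gte(n_ok, 18) # >= 90% of replicates
})
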