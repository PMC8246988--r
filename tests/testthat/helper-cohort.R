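# Shared fixtures, all built in code.

# Minimal valid 3-subject cohort data frames (1 control, 2 patients).
tiny_demographics <- function() {
  data.frame(
    subject_id = c("C001", "L001", "R001"),
    group = c("control", "left_tle", "right_tle"),
    sex = c("F", "M", "F"),
    age_years = c(40, 35, 50),
    onset_age_years = c(NA, 15, 20),
    duration_years = c(NA, 20, 30),
    ilae_outcome = c(NA, "ILAE1", "ILAE2plus"),
    hs_present = c(NA, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

tiny_fa <- function() {
  set.seed(99)
  df <- data.frame(subject_id = c("C001", "L001", "R001"))
  for (tr in tract_names()) df[[tr]] <- round(runif(3, 0.3, 0.5), 4)
  df
}

write_tiny_cohort <- function(dir = tempfile("cohort")) {
  dir.create(dir, recursive = TRUE)
  dem <- tiny_demographics()
  fa <- tiny_fa()
  write.csv(dem, file.path(dir, "demographics.csv"), row.names = FALSE,
            na = "", quote = FALSE)
  write.csv(fa, file.path(dir, "tract_fa.csv"), row.names = FALSE,
            na = "", quote = FALSE)
  list(dir = dir, demographics = file.path(dir, "demographics.csv"),
       tract_fa = file.path(dir, "tract_fa.csv"), dem = dem, fa = fa)
}

# Generator config with every systematic effect switched off.
null_config <- function(...) {
  generator_config(age_slope_per_year = 0, sex_offset = 0,
                   duration_slope_ipsi = 0, duration_slope_contra = 0,
                   heterogeneity_sd = 0, ...)
}

# All permutations of 1:n, for exact-enumeration oracles (small n only).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L)) {
    for (i in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
    }
  }
  out
}

# Cohort -> residuals -> distance set, at reduced reps for test speed.
quick_distance_set <- function(cohort, n_reps = 200, seed = 1) {
  res <- residualize(cohort$fa, cohort$subjects)
  compute_distance_set(res, cohort$subjects, n_reps = n_reps, seed = seed)
}
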