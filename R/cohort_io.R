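# Cohort I/O: demographics + tract-FA tables, validation, hemisphere maps.

#' Tract names used throughout the pipeline
#'
#' Ten limbic white-matter tracts: bilateral anterior thalamic radiation
#' (ATR), cingulum gyrus (CG), cingulum hippocampus (CH), fornix (F) and
#' uncinate fasciculus (UF). `.L`/`.R` denote hemisphere.
#'
#' @return character vector of the ten tract names, in canonical order.
#' @export
tract_names <- function() {
  as.vector(t(outer(tract_families(), c("L", "R"), paste, sep = ".")))
}

#' @rdname tract_names
#' @return `tract_families()`: the five tract family names without hemisphere.
#' @export
tract_families <- function() c("ATR", "CG", "CH", "F", "UF")

subject_groups <- function() c("control", "left_tle", "right_tle")

demographics_columns <- function() {
  c("subject_id", "group", "sex", "age_years", "onset_age_years",
    "duration_years", "ilae_outcome", "hs_present")
}

#' Map a subject group to hemisphere tract sets
#'
#' For patients, tracts are relabelled relative to the epileptogenic focus:
#' ipsilateral = same hemisphere as the focus. Controls have no focus and
#' keep plain left/right sets.
#'
#' @param group one of `"control"`, `"left_tle"`, `"right_tle"`.
#' @return a `hemisphere_map`: for patients, list with `ipsilateral_tracts`
#'   and `contralateral_tracts`; for controls, `left_tracts` and
#'   `right_tracts`. Each element has five tract names, one per family.
#' @export
#' @examples
#' hemisphere_map("left_tle")$ipsilateral_tracts
hemisphere_map <- function(group) {
  group <- match.arg(group, subject_groups())
  left <- paste0(tract_families(), ".L")
  right <- paste0(tract_families(), ".R")
  m <- switch(group,
    control   = list(left_tracts = left, right_tracts = right),
    left_tle  = list(ipsilateral_tracts = left, contralateral_tracts = right),
    right_tle = list(ipsilateral_tracts = right, contralateral_tracts = left))
  structure(c(m, list(group = group)), class = "hemisphere_map")
}

validate_subjects <- function(dem) {
  need <- demographics_columns()
  missing_cols <- setdiff(need, names(dem))
  tn_assert(length(missing_cols) == 0, "missing_column",
            paste("demographics table lacks column(s):",
                  paste(missing_cols, collapse = ", ")))
  tn_assert(!anyDuplicated(dem$subject_id), "duplicate_id",
            paste("duplicate subject_id:",
                  paste(unique(dem$subject_id[duplicated(dem$subject_id)]),
                        collapse = ", ")))
  bad_grp <- setdiff(unique(dem$group), subject_groups())
  tn_assert(length(bad_grp) == 0, "bad_token",
            paste("unknown group token(s):", paste(bad_grp, collapse = ", ")))
  bad_sex <- setdiff(unique(dem$sex), c("F", "M"))
  tn_assert(length(bad_sex) == 0, "bad_token",
            paste("unknown sex token(s):", paste(bad_sex, collapse = ", ")))
  tn_assert(all(is.finite(dem$age_years)) && all(dem$age_years >= 0),
            "bad_value", "age_years must be non-negative and present")

  is_ctrl <- dem$group == "control"
  ctrl_extra <- is_ctrl & (!is.na(dem$onset_age_years) |
                           !is.na(dem$duration_years) |
                           !is.na(dem$ilae_outcome) | !is.na(dem$hs_present))
  tn_assert(!any(ctrl_extra), "bad_value",
            paste("controls must not carry onset/duration/outcome/HS fields:",
                  paste(dem$subject_id[ctrl_extra], collapse = ", ")))
  one_of_two <- !is_ctrl & xor(is.na(dem$onset_age_years),
                               is.na(dem$duration_years))
  tn_assert(!any(one_of_two), "bad_value",
            "onset_age_years and duration_years must be both present or both absent")
  pat <- !is_ctrl & !is.na(dem$duration_years)
  # duration = age at scan - age at onset, allowing 1 year of rounding slack
  mismatch <- pat & abs(dem$duration_years -
                          (dem$age_years - dem$onset_age_years)) > 1.0
  tn_assert(!any(mismatch), "duration_inconsistent",
            paste("duration_years != age_years - onset_age_years (>1y) for:",
                  paste(dem$subject_id[mismatch], collapse = ", ")))
  bad_out <- !is.na(dem$ilae_outcome) &
    !dem$ilae_outcome %in% c("ILAE1", "ILAE2plus")
  tn_assert(!any(bad_out), "bad_token",
            "ilae_outcome must be ILAE1 or ILAE2plus when present")
  invisible(dem)
}

validate_fa <- function(fa_df) {
  need <- c("subject_id", tract_names())
  missing_cols <- setdiff(need, names(fa_df))
  tn_assert(length(missing_cols) == 0, "missing_column",
            paste("tract-FA table lacks column(s):",
                  paste(missing_cols, collapse = ", ")))
  tn_assert(!anyDuplicated(fa_df$subject_id), "duplicate_id",
            "duplicate subject_id in tract-FA table")
  vals <- as.matrix(fa_df[, tract_names()])
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    tn_error("fa_missing",
             sprintf("missing FA value for subject '%s', tract %s",
                     fa_df$subject_id[bad[1]], tract_names()[bad[2]]))
  }
  out <- vals <= 0 | vals >= 1
  if (any(out)) {
    bad <- which(out, arr.ind = TRUE)[1, ]
    tn_error("fa_bounds",
             sprintf("FA value %.4g outside (0,1) for subject '%s', tract %s",
                     vals[bad[1], bad[2]], fa_df$subject_id[bad[1]],
                     tract_names()[bad[2]]))
  }
  invisible(fa_df)
}

#' Read and validate a cohort
#'
#' Reads the demographics and tract-FA CSV files (comma-separated, UTF-8,
#' header row, empty string = absent), validates both, aligns them by
#' subject id and returns them sorted by id so that downstream seeded
#' resampling does not depend on the input row order.
#'
#' @param demographics_path path to `demographics.csv` with columns
#'   `subject_id, group, sex, age_years, onset_age_years, duration_years,
#'   ilae_outcome, hs_present`.
#' @param fa_path path to `tract_fa.csv` with columns `subject_id` plus the
#'   ten names of [tract_names()].
#' @return a list with `subjects` (data frame) and `fa` (numeric matrix,
#'   rownames = subject ids, columns = tracts).
#' @export
read_cohort <- function(demographics_path, fa_path) {
  tn_assert(file.exists(demographics_path), "missing_file",
            paste("no such file:", demographics_path))
  tn_assert(file.exists(fa_path), "missing_file",
            paste("no such file:", fa_path))
  header <- names(read.csv(demographics_path, nrows = 1))
  char_cols <- intersect(c("subject_id", "group", "sex", "ilae_outcome"),
                         header)
  dem <- read.csv(demographics_path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"),
                  colClasses = setNames(rep("character", length(char_cols)),
                                        char_cols))
  if ("hs_present" %in% names(dem)) dem$hs_present <- as.logical(dem$hs_present)
  fa_header <- names(read.csv(fa_path, nrows = 1))
  fa_df <- read.csv(fa_path, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"),
                    colClasses = if ("subject_id" %in% fa_header)
                      c(subject_id = "character"))
  as_cohort(dem, fa_df)
}

# Validate + align raw data frames into the canonical cohort structure.
as_cohort <- function(dem, fa_df) {
  validate_subjects(dem)
  validate_fa(fa_df)
  tn_assert(setequal(dem$subject_id, fa_df$subject_id), "id_mismatch",
            paste("subject ids differ between tables; only in demographics:",
                  paste(setdiff(dem$subject_id, fa_df$subject_id), collapse = ", "),
                  "; only in FA:",
                  paste(setdiff(fa_df$subject_id, dem$subject_id), collapse = ", ")))
  ord <- order(dem$subject_id)
  subjects <- dem[ord, demographics_columns()]
  rownames(subjects) <- NULL
  fa <- as.matrix(fa_df[match(subjects$subject_id, fa_df$subject_id),
                        tract_names()])
  rownames(fa) <- subjects$subject_id
  list(subjects = subjects, fa = fa)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: writes `demographics.csv` and `tract_fa.csv`
#' in the interchange dialect (absent fields as empty strings).
#'
#' @param cohort list with `subjects` and `fa` as returned by
#'   [read_cohort()] or [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dem_path <- file.path(dir, "demographics.csv")
  fa_path <- file.path(dir, "tract_fa.csv")
  write.csv(cohort$subjects, dem_path, row.names = FALSE, na = "",
            quote = FALSE)
  fa_df <- data.frame(subject_id = rownames(cohort$fa),
                      cohort$fa, check.names = FALSE)
  write.csv(fa_df, fa_path, row.names = FALSE, na = "", quote = FALSE)
  invisible(c(demographics = dem_path, tract_fa = fa_path))
}
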