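# End-to-end pipeline: cohort -> residuals -> distances -> associations ->
# onset -> outcome -> robustness, from a single config, with a manifest.

#' Build a pipeline configuration
#'
#' Exactly one of `input` (paths to demographics/tract-FA CSVs) or
#' `generator` (a [generator_config()] or list of its arguments) must be
#' given. All stage seeds are derived deterministically from the single
#' top-level `seed`.
#'
#' @param input optional list with `demographics` and `tract_fa` paths.
#' @param generator optional [generator_config()] or argument list.
#' @param covariates list: `fit_population`, `huber_k`, `max_iter`, `tol`.
#' @param distances list: `n_subsample`, `n_reps`, `estimator`.
#' @param association list: `alpha`.
#' @param robustness list: `m`, `n_reps`, optional `m_range` for a sweep.
#' @param onset list: `n_subsample`, `n_reps`.
#' @param normality list: `n_sim`.
#' @param seed top-level integer seed.
#' @param out_dir output directory for [run_pipeline()].
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, generator = NULL,
                            covariates = list(), distances = list(),
                            association = list(), robustness = list(),
                            onset = list(), normality = list(),
                            seed = 1L, out_dir = "tractnorm_output") {
  defaults <- function(given, def) utils::modifyList(def, as.list(given))
  cfg <- list(
    input = input,
    generator = generator,
    covariates = defaults(covariates, list(fit_population = "controls_only",
                                           huber_k = 1.345, max_iter = 100,
                                           tol = 1e-8)),
    distances = defaults(distances, list(n_subsample = 24, n_reps = 1000,
                                         estimator = "ledoit_wolf_linear")),
    association = defaults(association, list(alpha = 0.05)),
    robustness = defaults(robustness, list(m = 30, n_reps = 1000,
                                           m_range = NULL)),
    onset = defaults(onset, list(n_subsample = 54, n_reps = 1000)),
    normality = defaults(normality, list(n_sim = 10000)),
    seed = as.integer(seed), out_dir = out_dir)
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param config a list as from [pipeline_config()] or a path to a YAML
#'   file with the same structure.
#' @return the validated `pipeline_config`, invisibly usable downstream.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, config)
    return(config)
  }
  tn_assert(xor(is.null(config$input), is.null(config$generator)),
            "bad_config",
            "exactly one of 'input' and 'generator' must be given")
  if (!is.null(config$input)) {
    tn_assert(all(c("demographics", "tract_fa") %in% names(config$input)),
              "bad_config", "input needs 'demographics' and 'tract_fa' paths")
  }
  structure(config, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load or synthesise the cohort, residualize covariates, compute
#' the distance set, test duration associations (per group and combined),
#' extrapolate to onset, compare surgical outcomes, run normality checks
#' and the consistency report. Writes `distances.csv`, `associations.csv`,
#' `onset.json`, `cohort_tests.csv`, `outcome_tests.csv`,
#' `consistency.csv` and `run_manifest.json` to `out_dir`; byte-identical
#' outputs for a fixed config and seed.
#'
#' @param config a `pipeline_config`, raw list, or YAML path.
#' @param out_dir overrides `config$out_dir` if given.
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  config <- validate_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  log_line <- function(...) if (!quiet) message(sprintf(...))

  stage <- "load_cohort"
  result <- tryCatch({
    cohort <- if (!is.null(config$input)) {
      read_cohort(config$input$demographics, config$input$tract_fa)
    } else {
      gen <- config$generator
      if (!inherits(gen, "generator_config")) {
        gen <- do.call(generator_config, as.list(gen))
      }
      generate_cohort(gen, seed = derive_seed(seed, "generate"))
    }
    log_line("load_cohort: %d subjects (%d controls)",
             nrow(cohort$subjects),
             sum(cohort$subjects$group == "control"))

    stage <- "residualize"
    resid <- residualize(cohort$fa, cohort$subjects,
                         fit_population = config$covariates$fit_population,
                         k = config$covariates$huber_k,
                         max_iter = config$covariates$max_iter,
                         tol = config$covariates$tol)
    log_line("residualize: 10 tracts on %s", config$covariates$fit_population)

    stage <- "distances"
    ds <- compute_distance_set(resid, cohort$subjects,
                               n_subsample = config$distances$n_subsample,
                               n_reps = config$distances$n_reps,
                               seed = derive_seed(seed, "distances"),
                               estimator = config$distances$estimator)
    log_line("distances: %d subjects x 12 measures, %d reps each",
             nrow(ds), config$distances$n_reps)

    stage <- "associations"
    alpha <- config$association$alpha
    assoc <- rbind(duration_associations(ds, "per_group", alpha = alpha),
                   duration_associations(ds, "combined", alpha = alpha))
    log_line("associations: %d results, %d Bonferroni-significant",
             nrow(assoc), sum(assoc$significant_bonferroni))

    stage <- "onset"
    onset <- onset_analysis(ds, n_subsample = config$onset$n_subsample,
                            n_reps = config$onset$n_reps,
                            seed = derive_seed(seed, "onset"))
    log_line("onset: beta0 ipsi %.3f contra %.3f",
             onset$ipsilateral$beta0, onset$contralateral$beta0)

    stage <- "cohort_tests"
    ctests <- cohort_summary_tests(cohort$subjects)
    ntests <- normality_checks(resid, cohort$subjects, alpha = alpha,
                               n_sim = config$normality$n_sim,
                               seed = derive_seed(seed, "normality"))
    log_line("cohort_tests: %d demographic + %d normality checks",
             nrow(ctests), nrow(ntests))

    stage <- "outcome"
    outc <- outcome_comparison(ds, alpha = alpha)
    log_line("outcome: %d tests", nrow(outc))

    stage <- "robustness"
    cons <- full_consistency_report(ds, m = config$robustness$m,
                                    n_reps = config$robustness$n_reps,
                                    alpha = alpha,
                                    seed = derive_seed(seed, "robustness"))
    if (!is.null(config$robustness$m_range)) {
      sweep_rows <- list()
      for (g in c("left_tle", "right_tle")) {
        d <- ds[ds$group == g & !is.na(ds$duration_years), ]
        for (meas in c("md_ipsi", "md_contra")) {
          sw <- consistency_sweep(d[[meas]], d$duration_years,
                                  m_range = config$robustness$m_range,
                                  n_reps = config$robustness$n_reps,
                                  alpha = alpha, h = 2,
                                  direction = "positive",
                                  seed = derive_seed(seed, "sweep", g, meas))
          sw$measure_id <- meas
          sw$group <- g
          sweep_rows[[length(sweep_rows) + 1]] <- sw
        }
      }
      cons <- rbind(cons, do.call(rbind, sweep_rows))
    }
    log_line("robustness: %d kappa values", nrow(cons))

    list(cohort = cohort, residuals = resid, distances = ds,
         associations = assoc, onset = onset, cohort_tests = ctests,
         normality = ntests, outcome_tests = outc, consistency = cons)
  }, tractnorm_error = function(e) {
    tn_error("pipeline_stage",
             sprintf("pipeline failed at stage '%s': %s", stage,
                     conditionMessage(e)))
  })

  paths <- write_report(result, config, out_dir)
  result$paths <- paths
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report <- function(result, config, out_dir) {
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    write.csv(df, path, row.names = FALSE, na = "")
    path
  }
  paths <- c(
    distances = wcsv(as.data.frame(result$distances), "distances.csv"),
    associations = wcsv(result$associations, "associations.csv"),
    cohort_tests = wcsv(rbind(
      cbind(result$cohort_tests, measure_id = NA_character_)[
        , c("test_name", "comparison", "statistic", "df", "p_value",
            "tails", "measure_id")],
      cbind(result$normality, comparison = NA_character_)[
        , c("test_name", "comparison", "statistic", "df", "p_value",
            "tails", "measure_id")]), "cohort_tests.csv"),
    outcome_tests = wcsv(result$outcome_tests, "outcome_tests.csv"),
    consistency = wcsv(result$consistency, "consistency.csv"))

  onset_path <- file.path(out_dir, "onset.json")
  jsonlite::write_json(lapply(result$onset, unclass), onset_path,
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "tractnorm",
    version = as.character(utils::packageVersion("tractnorm")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    derived_seeds = list(generate = derive_seed(config$seed, "generate"),
                         distances = derive_seed(config$seed, "distances"),
                         onset = derive_seed(config$seed, "onset"),
                         normality = derive_seed(config$seed, "normality"),
                         robustness = derive_seed(config$seed, "robustness")),
    n_subjects = nrow(result$distances),
    config = config[setdiff(names(config), c("input", "generator"))],
    generator = if (!is.null(config$generator))
      lapply(unclass(config$generator), function(x)
        if (is.matrix(x)) NULL else x))
  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  c(paths, onset = onset_path, manifest = manifest_path)
}
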