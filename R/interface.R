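# Canonical trials.csv schema. Comma-delimited UTF-8, missing values empty,
# trial 0-based, transition in {common, rare} (accepted case-insensitively).
trials_columns <- c("subject_id", "group", "severity", "trial", "s1_choice",
                    "s1_rt_ms", "transition", "s2_state", "s2_choice",
                    "s2_rt_ms", "reward", "missed_stage")

#' Write a cohort's trial table to CSV
#'
#' @param cohort A `twostep_cohort`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(cohort, path) {
  utils::write.csv(cohort$trials[, trials_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Write a cohort's subject table to CSV
#'
#' @param cohort A `twostep_cohort`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(cohort, path) {
  utils::write.csv(cohort$subjects, path, row.names = FALSE, na = "")
  invisible(path)
}

check_codes <- function(x, allowed, column) {
  bad <- which(!is.na(x) & !x %in% allowed)
  if (length(bad)) {
    stop("invalid value in column '", column, "' at row ", bad[1], ": ",
         x[bad[1]])
  }
}

#' Read a trial table (and optional subject table) from CSV
#'
#' Validates the canonical schema: mandatory columns must be present (error
#' names the missing column), unknown columns produce a warning and are
#' dropped, out-of-range codes raise an error naming the first offending
#' row. `transition` and `missed_stage` are accepted case-insensitively and
#' canonicalized to lower case. When no subject file is given, the subject
#' table is reconstructed from the trial rows.
#'
#' @param path Path to trials.csv.
#' @param subjects_path Optional path to subjects.csv.
#' @return A `twostep_cohort`.
#' @export
read_trials <- function(path, subjects_path = NULL) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trials_columns, names(tr))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(tr), trials_columns)
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  }
  tr <- tr[, trials_columns]
  tr$subject_id <- as.character(tr$subject_id)
  tr$group <- as.character(tr$group)
  tr$transition <- tolower(as.character(tr$transition))
  tr$transition[tr$transition == ""] <- NA_character_
  tr$missed_stage <- tolower(as.character(tr$missed_stage))
  check_codes(tr$s1_choice, 0:1, "s1_choice")
  check_codes(tr$s2_choice, 0:1, "s2_choice")
  check_codes(tr$s2_state, 0:1, "s2_state")
  check_codes(tr$reward, 0:1, "reward")
  check_codes(tr$transition, c("common", "rare"), "transition")
  check_codes(tr$missed_stage, c("none", "stage1", "stage2"), "missed_stage")
  for (col in c("s1_choice", "s2_choice", "s2_state", "reward", "trial")) {
    tr[[col]] <- as.integer(tr[[col]])
  }
  if (!is.null(subjects_path)) {
    subjects <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)
    subjects$subject_id <- as.character(subjects$subject_id)
  } else if (nrow(tr)) {
    subjects <- unique(tr[, c("subject_id", "group", "severity")])
    rownames(subjects) <- NULL
  } else {
    subjects <- data.frame(subject_id = character(0), group = character(0),
                           severity = numeric(0), stringsAsFactors = FALSE)
  }
  new_cohort(subjects, tr)
}

#' Read a run configuration from YAML
#'
#' Keys: `task` (any [task_config()] argument), `seed`, `out_dir`,
#' `input` (paths `trials`/`subjects`, mutually exclusive with a generated
#' cohort), `analyses` (logical switches `choice`, `valence`, `rt`,
#' `severity`, and a `covariates` character vector), and `random`
#' (random-effects structure for the stay regressions).
#'
#' @param path YAML file.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full analysis pipeline
#'
#' Generate (or load) a cohort, apply the engagement filters, build the
#' lagged table, run the requested choice and response-time analyses, and
#' write every table plus a run manifest to `out_dir`. Any stage failure
#' aborts with the stage name; tables already written are retained.
#'
#' @param config Named list (see [read_run_config()]): `task`, `seed`,
#'   `out_dir`, optional `input` (paths), `analyses` switches, `random`.
#'   When no `input` is given, a synthetic cohort from [default_specs()] is
#'   generated; supplying both an input and expecting generation is an
#'   error by construction (the input wins is never silently chosen).
#' @param specs Optional list of [group_spec()]s overriding
#'   [default_specs()] for generated cohorts.
#' @return Invisible list with all intermediate and final results:
#'   `cohort`, `filter`, `lagged`, `stay_fit`, `valence`, `reward_rate`,
#'   `rt2_anova`, `rt1_anova`, `severity_cor`, `covariate_fits`, `manifest`.
#' @export
run_pipeline <- function(config = list(), specs = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(obj, name) {
    if (!is.null(out_dir)) {
      utils::write.csv(obj, file.path(out_dir, name), row.names = FALSE)
    }
  }
  analyses <- utils::modifyList(
    list(choice = TRUE, valence = TRUE, rt = TRUE, severity = TRUE,
         covariates = character(0)),
    if (is.null(config$analyses)) list() else config$analyses
  )
  random <- if (is.null(config$random)) "slopes" else config$random

  task <- stage("config", do.call(task_config,
                                  if (is.null(config$task)) list()
                                  else config$task))

  if (!is.null(config$input)) {
    if (!is.null(specs)) stop("give either an input or a cohort spec, not both")
    message("stage load: reading ", config$input$trials)
    cohort <- stage("load", read_trials(config$input$trials,
                                        config$input$subjects))
  } else {
    if (is.null(specs)) specs <- default_specs()
    message("stage generate: simulating cohort (seed ", seed, ")")
    cohort <- stage("generate", sample_cohort(specs, task, seed = seed))
    if (!is.null(out_dir)) {
      write_trials(cohort, file.path(out_dir, "trials.csv"))
      write_subjects(cohort, file.path(out_dir, "subjects.csv"))
    }
  }
  message(sprintf("stage filter: %d subjects in", nrow(cohort$subjects)))
  flt <- stage("filter", apply_engagement_filters(cohort))
  emit(flt$report, "filter_report.csv")
  message(sprintf("stage filter: %d excluded, %d kept",
                  sum(flt$report$excluded), nrow(flt$cohort$subjects)))

  lagged <- stage("lag", build_lagged_table(flt$cohort))
  message(sprintf("stage lag: %d rows built", nrow(lagged)))

  out <- list(cohort = cohort, filter = flt, lagged = lagged)

  if (isTRUE(analyses$choice)) {
    out$stay_fit <- stage("choice", fit_stay_regression(lagged,
                                                        random = random))
    emit(out$stay_fit$coefficients, "stay_coefficients.csv")
    out$reward_rate <- stage("choice", reward_rate_comparison(flt$cohort))
  }
  if (isTRUE(analyses$valence)) {
    out$valence <- stage("valence", fit_valence_split(lagged,
                                                      random = random))
    emit(out$valence$rewarded$coefficients, "stay_after_reward.csv")
    emit(out$valence$unrewarded$coefficients, "stay_after_noreward.csv")
  }
  if (length(analyses$covariates)) {
    out$covariate_fits <- lapply(analyses$covariates, function(cv) {
      stage(paste0("covariate:", cv),
            fit_covariate_regression(lagged, cv, random = random))
    })
    names(out$covariate_fits) <- analyses$covariates
  }
  if (isTRUE(analyses$rt)) {
    out$rt2_anova <- stage("rt", rt2_transition_anova(flt$cohort))
    out$rt1_anova <- stage("rt", rt1_outcome_anova(flt$cohort))
    emit(out$rt2_anova$table, "rt2_transition_anova.csv")
    emit(out$rt2_anova$posthoc, "rt2_posthoc.csv")
    emit(out$rt1_anova$table, "rt1_outcome_anova.csv")
    emit(out$rt1_anova$posthoc, "rt1_posthoc.csv")
  }
  if (isTRUE(analyses$severity) && any(flt$cohort$subjects$group == "PG")) {
    out$severity_cor <- stage("severity",
                              severity_rt_correlation(flt$cohort))
    if (!is.null(out_dir)) {
      emit(data.frame(r = out$severity_cor$r, p = out$severity_cor$p,
                      n = out$severity_cor$n), "severity_correlation.csv")
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("twosteptask")),
    seed = seed,
    task = unclass(task),
    analyses = analyses,
    random = random,
    n_subjects_in = nrow(cohort$subjects),
    n_subjects_excluded = sum(flt$report$excluded),
    n_lagged_rows = nrow(lagged)
  )
  if (!is.null(out_dir)) {
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  out$manifest <- manifest
  invisible(out)
}
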