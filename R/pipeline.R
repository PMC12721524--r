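#' Experiment orchestration
#'
#' [run_experiment()] runs the whole study design from one configuration
#' object: phantom cohort -> derived maps -> channel stacks -> cross-validated
#' predictions per configuration -> censored Dice records and summaries ->
#' paired one-tailed comparisons against baseline. Every stage's outputs are
#' written as files under the experiment directory so stages can be audited
#' or rescored independently, and the whole run is deterministic given the
#' configured seed.
#'
#' @name pipeline
NULL

#' Build and validate an experiment configuration
#'
#' @param phantom a [phantom_spec()] describing the cohort.
#' @param n_cases number of phantom cases.
#' @param configurations channel configurations to run; must include
#'   `"baseline"` (comparisons need it).
#' @param alpha ratio-map denominator offset.
#' @param n_folds cross-validation folds (>= 2).
#' @param seed integer seed for fold assignment and classifier subsampling
#'   (the phantom has its own seed inside `phantom`).
#' @param subsample classifier training voxels per class.
#' @param smooth_radius majority-vote smoothing radius (0 disables).
#' @param censor_policy Dice censoring policy, see [score_case()].
#' @param family_alpha family-wise alpha for the Bonferroni threshold.
#' @param out_dir experiment output directory.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(), n_cases = 40L,
                              configurations = c("baseline", "ratio", "combined"),
                              alpha = 1e-6, n_folds = 5L, seed = 1L,
                              subsample = 5000, smooth_radius = 0L,
                              censor_policy = "dice1", family_alpha = 0.05,
                              out_dir = tempfile("experiment")) {
  stopifnot(inherits(phantom, "phantom_spec"), n_cases >= 1)
  unknown <- setdiff(configurations, c("baseline", "ratio", "combined"))
  if (length(unknown)) {
    stop("unknown configurations: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"baseline" %in% configurations) {
    stop("configurations must include baseline: comparisons are against it",
         call. = FALSE)
  }
  if (n_folds < 2) stop("n_folds must be at least 2", call. = FALSE)
  structure(list(phantom = phantom, n_cases = as.integer(n_cases),
                 configurations = configurations, alpha = alpha,
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 subsample = subsample, smooth_radius = smooth_radius,
                 censor_policy = censor_policy, family_alpha = family_alpha,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full experiment
#'
#' @param config an [experiment_config()].
#' @return Invisibly, a list with `manifest`, `records`, `summary_censored`,
#'   `summary_uncensored`, `comparisons`, `folds`, `qc`, and `paths` to the
#'   files written.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  manifest <- generate_cohort(config$phantom, config$n_cases,
                              file.path(out, "cohort"))
  cases <- lapply(seq_len(nrow(manifest)), function(i)
    read_phantom_case(manifest[i, ]))
  names(cases) <- manifest$case_id
  refs <- lapply(cases, function(cs)
    list(labels = cs$labels, brain_mask = cs$brain_mask))

  pred_dir <- file.path(out, "predictions")
  dir.create(pred_dir, showWarnings = FALSE)
  predictions <- list()
  qc <- list()
  folds <- NULL
  for (cfg in config$configurations) {
    stacks <- lapply(cases, build_channel_stack, configuration = cfg,
                     alpha = config$alpha)
    qc[[cfg]] <- lapply(stacks, attr, "qc")
    cv <- cross_validate_cases(stacks, refs, n_folds = config$n_folds,
                               seed = config$seed, subsample = config$subsample,
                               smooth_radius = config$smooth_radius)
    folds <- cv$folds  # same seed for every configuration: one assignment
    for (id in names(cv$predictions)) {
      write_volume(cv$predictions[[id]],
                   file.path(pred_dir, sprintf("%s_pred_%s.nii.gz", id, cfg)),
                   datatype = "int16")
    }
    predictions[[cfg]] <- cv$predictions
  }
  write.csv(folds, file.path(out, "folds.csv"), row.names = FALSE)
  jsonlite::write_json(qc, file.path(out, "qc.json"), auto_unbox = TRUE,
                       digits = NA)

  records <- score_records(predictions,
                           lapply(refs, `[[`, "labels"),
                           censor_policy = config$censor_policy)
  write.csv(records, file.path(out, "records.csv"), row.names = FALSE)

  summary_censored <- summarize_dice(records, censor = TRUE)
  summary_uncensored <- summarize_dice(records, censor = FALSE)
  write.csv(summary_censored, file.path(out, "summary_censored.csv"),
            row.names = FALSE)
  write.csv(summary_uncensored, file.path(out, "summary_uncensored.csv"),
            row.names = FALSE)

  test_models <- setdiff(config$configurations, "baseline")
  comparisons <- NULL
  if (length(test_models)) {
    comparisons <- compare_models(records, "baseline", test_models,
                                  family_alpha = config$family_alpha)
    write.csv(comparisons, file.path(out, "comparisons.csv"), row.names = FALSE)
  }

  run_log <- list(
    seed = config$seed, phantom_seed = config$phantom$seed,
    n_cases = config$n_cases, n_folds = config$n_folds,
    configurations = config$configurations, alpha = config$alpha,
    censor_policy = config$censor_policy, family_alpha = config$family_alpha,
    grid_shape = config$phantom$grid_shape,
    noise_sd = config$phantom$noise_sd,
    bias_field_amplitude = config$phantom$bias_field_amplitude
  )
  jsonlite::write_json(run_log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(manifest = manifest, records = records,
                 summary_censored = summary_censored,
                 summary_uncensored = summary_uncensored,
                 comparisons = comparisons, folds = folds, qc = qc,
                 paths = list(
                   out_dir = out,
                   manifest = file.path(out, "cohort", "manifest.csv"),
                   records = file.path(out, "records.csv"),
                   summary_censored = file.path(out, "summary_censored.csv"),
                   summary_uncensored = file.path(out, "summary_uncensored.csv"),
                   comparisons = if (length(test_models))
                     file.path(out, "comparisons.csv") else NULL,
                   folds = file.path(out, "folds.csv"),
                   qc = file.path(out, "qc.json"),
                   run_log = file.path(out, "run_log.json"),
                   predictions = pred_dir)))
}
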