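#' Build a run configuration
#'
#' A single declarative object driving simulate -> preprocess -> extract ->
#' split -> (tune) -> train -> evaluate. Any section may be given as a
#' plain named list (e.g. parsed from YAML); missing fields take the
#' package defaults. Validation failures are aggregated and reported
#' together.
#'
#' @param synthetic Named list of [synthetic_spec()] arguments, or `NULL`
#'   when `manifest` is given.
#' @param manifest Path to a YAML dataset manifest, or `NULL` for
#'   synthetic data.
#' @param subjects,sessions Ids for synthetic generation.
#' @param filter Named list of [filter_spec()] arguments (minus `fs`).
#' @param window Named list of [window_spec()] arguments.
#' @param features Named list of [feature_config()] arguments.
#' @param backend Classifier backend name.
#' @param train_frac Temporal split fraction.
#' @param tune_enabled Run hyperparameter optimization.
#' @param optimizer `"lshade"` or `"random"`.
#' @param lshade Named list of [lshade_config()] arguments.
#' @param fit_seed Seed for classifier fits.
#' @param out_dir Optional output directory for JSON artifacts and the run
#'   log.
#' @return An object of class `run_config`.
#' @export
run_config <- function(synthetic = list(), manifest = NULL,
                       subjects = "sub1", sessions = "S1",
                       filter = list(), window = list(), features = list(),
                       backend = "et", train_frac = 0.7,
                       tune_enabled = FALSE, optimizer = "lshade",
                       lshade = list(np_init = 20, max_gen = 20, seed = 1),
                       fit_seed = 0L, out_dir = NULL) {
  problems <- character(0)
  note <- function(msg) problems <<- c(problems, msg)
  if (is.null(manifest) && is.null(synthetic))
    note("either a manifest path or a synthetic section is required")
  if (!is.null(manifest) && !file.exists(manifest))
    note(sprintf("manifest file not found: %s", manifest))
  if (train_frac <= 0 || train_frac >= 1)
    note("train_frac must lie strictly between 0 and 1")
  spec <- tryCatch(do.call(synthetic_spec, synthetic),
                   error = function(e) { note(conditionMessage(e)); NULL })
  wspec <- tryCatch(do.call(window_spec, window),
                    error = function(e) { note(conditionMessage(e)); NULL })
  fcfg <- tryCatch(do.call(feature_config, features),
                   error = function(e) { note(conditionMessage(e)); NULL })
  lcfg <- tryCatch(do.call(lshade_config, lshade),
                   error = function(e) { note(conditionMessage(e)); NULL })
  tryCatch(get_backend(backend),
           error = function(e) note(conditionMessage(e)))
  if (length(problems))
    stop("run_config: invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  structure(list(synthetic = spec, manifest = manifest, subjects = subjects,
                 sessions = sessions, filter = filter, window = wspec,
                 features = fcfg, backend = backend, train_frac = train_frac,
                 tune_enabled = tune_enabled, optimizer = optimizer,
                 lshade = lcfg, fit_seed = as.integer(fit_seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose top-level keys are [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(cfg)), tmp)
  unname(tools::md5sum(tmp))
}

#' Run a full experiment from a configuration
#'
#' Generates or loads the dataset, applies the two-stage preprocessing,
#' extracts the windowed feature matrix, performs the temporal split per
#' subject, trains and evaluates the backend at default hyperparameters,
#' optionally tunes with L-SHADE and re-evaluates, and (with two or more
#' subjects and tuning enabled) runs a paired t-test on the
#' default-vs-tuned per-subject accuracies. When `out_dir` is set, JSON
#' reports and a run log (seeds, config hash, stage row counts) are
#' written there.
#'
#' @param cfg A [run_config()].
#' @return An `experiment_report`: per-subject default and tuned
#'   `eval_report`s, chosen hyperparameters, and the t-test when
#'   applicable.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log_lines <- c(sprintf("config_hash: %s", config_hash(cfg)),
                 sprintf("fit_seed: %d", cfg$fit_seed))
  records <- if (!is.null(cfg$manifest)) {
    load_dataset(read_manifest(cfg$manifest))
  } else {
    generate_records(cfg$synthetic, cfg$subjects, cfg$sessions)
  }
  fs <- records[[1L]]$fs
  fspec <- do.call(filter_spec, c(list(fs = fs), cfg$filter))
  records <- lapply(records, apply_preprocessing, spec = fspec)
  fm <- extract_feature_matrix(records, cfg$window, cfg$features)
  log_lines <- c(log_lines,
                 sprintf("records: %d, windows: %d, features: %d",
                         length(records), nrow(fm$values), ncol(fm$values)))
  subjects <- unique(fm$subject)
  per_subject <- lapply(subjects, function(sub) {
    sub_fm <- fm_rows(fm, which(fm$subject == sub))
    parts <- temporal_split(sub_fm, cfg$train_frac)
    default_model <- train_classifier(cfg$backend, list(), parts$train,
                                      seed = cfg$fit_seed)
    default_report <- evaluate(default_model, parts$test)
    out <- list(subject = sub, default_report = default_report,
                default_hp = default_et_params())
    if (isTRUE(cfg$tune_enabled)) {
      tn <- tune(parts$train, cfg$backend, cfg = cfg$lshade,
                 optimizer = cfg$optimizer, fit_seed = cfg$fit_seed)
      tuned_model <- train_classifier(cfg$backend, tn$best_hp, parts$train,
                                      seed = cfg$fit_seed)
      out$tuned_report <- evaluate(tuned_model, parts$test)
      out$tuned_hp <- tn$best_hp
      out$tune_trace <- tn$trace
    }
    out
  })
  names(per_subject) <- subjects
  report <- list(per_subject = per_subject, config_hash = config_hash(cfg))
  if (isTRUE(cfg$tune_enabled) && length(subjects) >= 2L) {
    a <- vapply(per_subject, function(p) p$tuned_report$accuracy, numeric(1))
    b <- vapply(per_subject, function(p) p$default_report$accuracy, numeric(1))
    report$ttest <- tryCatch(paired_ttest(a, b), error = function(e)
      list(error = conditionMessage(e)))
  }
  class(report) <- "experiment_report"
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sub in subjects) {
      p <- per_subject[[sub]]
      report_to_json(p$default_report,
                     file.path(cfg$out_dir, sprintf("%s_default.json", sub)))
      if (!is.null(p$tuned_report)) {
        report_to_json(p$tuned_report,
                       file.path(cfg$out_dir, sprintf("%s_tuned.json", sub)))
        writeLines(jsonlite::toJSON(p$tuned_hp, auto_unbox = TRUE),
                   file.path(cfg$out_dir, sprintf("%s_best_hp.json", sub)))
        utils::write.csv(p$tune_trace,
                         file.path(cfg$out_dir, sprintf("%s_tune_trace.csv", sub)),
                         row.names = FALSE)
      }
    }
    writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  for (p in x$per_subject) {
    cat(sprintf("subject %s: default accuracy %.2f%%",
                p$subject, 100 * p$default_report$accuracy))
    if (!is.null(p$tuned_report))
      cat(sprintf("  tuned accuracy %.2f%%", 100 * p$tuned_report$accuracy))
    cat("\n")
  }
  if (!is.null(x$ttest) && is.null(x$ttest$error))
    cat(sprintf("paired t-test (tuned vs default): t = %.3f, p = %.4g\n",
                x$ttest$t, x$ttest$p))
  invisible(x)
}
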