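#' Assemble the trial feature table for a cohort of preprocessed trials
#'
#' Runs detection, cleanup, segmentation, and feature aggregation for each
#' trial and binds the 248-feature vectors into a participants-by-features
#' matrix.
#'
#' @param trials A list of filtered `uniform_trial` objects.
#' @param cleanup A [cleanup_config()].
#' @param fft_len Spectral zero-padding length.
#' @return A list: `X` (matrix, named rows = participants, 248 columns),
#'   `step_counts`, `strike_counts`, `strikes` (list of cleaned series).
#' @export
cohort_features <- function(trials, cleanup = cleanup_config(),
                            fft_len = 128) {
  ids <- vapply(trials, function(tr) tr$participant_id, character(1))
  res <- lapply(trials, trial_features, cleanup = cleanup,
                fft_len = fft_len)
  X <- do.call(rbind, lapply(res, function(r) r$features))
  rownames(X) <- ids
  list(X = X,
       step_counts = vapply(res, function(r) r$step_count, numeric(1)),
       strike_counts = vapply(res, function(r) nrow(r$strikes), numeric(1)),
       strikes = lapply(res, function(r) r$strikes))
}

read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the full balance-confidence pipeline on a trial directory
#'
#' Executes preprocess -> foot-strike cleanup -> feature extraction ->
#' feature selection + random-forest LOOCV on a directory holding one
#' `trial_<participant_id>.csv` per participant and a `cohort.csv`
#' (`participant_id,abc_score,fall_history`). Writes the per-step and
#' trial feature CSVs, per-fold predictions, selected features, and a
#' report (JSON and Markdown) into `out_dir`. Fall history is carried as
#' metadata only, never used as a feature.
#'
#' @param input_dir Directory with trial CSVs and `cohort.csv`.
#' @param out_dir Output directory.
#' @param seed Integer seed for the classifier.
#' @param selection Feature-selection mode: `"global"` (CFS once on the
#'   full cohort, the default) or `"nested"` (CFS inside every fold;
#'   leakage-safe).
#' @param preprocess A [preprocess_config()].
#' @param cleanup A [cleanup_config()].
#' @param forest A [forest_config()]; its seed is overridden by `seed`.
#' @param fft_len Spectral zero-padding length.
#' @param abc_threshold Confidence threshold in percent.
#' @return A `run_report` list: per-stage counts, selected features,
#'   confusion matrix, metrics, config echo.
#' @export
run_pipeline <- function(input_dir, out_dir = NULL, seed = 1L,
                         selection = c("global", "nested"),
                         preprocess = preprocess_config(),
                         cleanup = cleanup_config(),
                         forest = forest_config(),
                         fft_len = 128, abc_threshold = 80) {
  selection <- match.arg(selection)
  cohort_path <- file.path(input_dir, "cohort.csv")
  if (!file.exists(cohort_path))
    stop("cohort file not found: ", cohort_path)
  cohort <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  if (anyDuplicated(cohort$participant_id))
    stop("duplicate participant_id in cohort file")
  trial_paths <- file.path(input_dir,
                           paste0("trial_", cohort$participant_id, ".csv"))
  missing <- !file.exists(trial_paths)
  if (any(missing))
    stop("stage preprocess: missing trial file(s) for participant(s) ",
         paste(cohort$participant_id[missing], collapse = ", "))

  trials <- lapply(seq_along(trial_paths), function(i)
    preprocess_trial(load_trial(trial_paths[i], preprocess$axis_map,
                                participant_id = cohort$participant_id[i]),
                     preprocess))
  feats <- cohort_features(trials, cleanup = cleanup, fft_len = fft_len)
  y <- label_confidence(cohort$abc_score, threshold = abc_threshold)

  forest$seed <- as.integer(seed)
  cv <- loocv(feats$X, y, cfg = forest, selection = selection)

  report <- list(
    package_version = as.character(utils::packageVersion("gaitconf")),
    seed = as.integer(seed),
    selection = selection,
    config = list(target_rate_hz = preprocess$target_rate_hz,
                  filter_order = preprocess$filter_order,
                  cutoff_hz = preprocess$cutoff_hz,
                  gap_factor = cleanup$gap_factor,
                  locking_fraction = cleanup$locking_fraction,
                  fft_len = fft_len, n_trees = forest$n_trees,
                  abc_threshold = abc_threshold),
    stages = list(
      n_participants = nrow(cohort),
      samples = vapply(trials, function(tr) tr$n_samples, numeric(1)),
      strikes = feats$strike_counts,
      steps = feats$step_counts
    ),
    selected_features = cv$selected,
    confusion = unclass(cv$confusion),
    metrics = unclass(cv$metrics),
    n_models = cv$n_models
  )
  class(report) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    feat_df <- data.frame(participant_id = rownames(feats$X),
                          step_count = feats$step_counts, feats$X,
                          check.names = FALSE)
    data.table::fwrite(feat_df, file.path(out_dir, "trial_features.csv"))
    preds <- cv$predictions
    preds$participant_id <- cohort$participant_id
    utils::write.csv(preds[, c("participant_id", "truth", "predicted")],
                     file.path(out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    if (!is.null(cv$selected))
      writeLines(cv$selected, file.path(out_dir, "selected_features.txt"))
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(format_report_md(report), file.path(out_dir, "report.md"))
  }
  report
}

format_report_md <- function(report) {
  cm <- report$confusion
  m <- report$metrics
  c("# Balance-confidence classification report",
    "",
    sprintf("- package gaitconf %s, seed %d, selection mode: %s",
            report$package_version, report$seed, report$selection),
    sprintf("- participants: %d; LOOCV models trained: %d",
            report$stages$n_participants, report$n_models),
    sprintf("- strikes per trial (median): %g; steps per trial (median): %g",
            stats::median(report$stages$strikes),
            stats::median(report$stages$steps)),
    if (!is.null(report$selected_features))
      sprintf("- selected features (%d): %s",
              length(report$selected_features),
              paste(report$selected_features, collapse = ", ")),
    "",
    "## Confusion matrix (rows = true, positive class = high confidence)",
    "",
    "| | pred. high | pred. low |",
    "|---|---|---|",
    sprintf("| true high | %d | %d |", cm$tp, cm$fn),
    sprintf("| true low | %d | %d |", cm$fp, cm$tn),
    "",
    sprintf("accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%, precision %.1f%% (%d / %d correct)",
            m$accuracy, m$sensitivity, m$specificity, m$precision,
            m$n_correct, m$n))
}

#' Per-item summary of ABC questionnaire responses
#'
#' For each of the 16 ABC items: the mean score and the number of 0% and
#' 100% confidence responses across participants.
#'
#' @param item_table Numeric matrix or data.frame, participants by 16
#'   items, scores in \[0, 100\].
#' @return A data.frame with columns `item`, `mean_score`, `n_zero`,
#'   `n_full`.
#' @export
summarize_abc <- function(item_table) {
  m <- as.matrix(item_table)
  if (ncol(m) != 16)
    stop("ABC item table must have exactly 16 columns, got ", ncol(m))
  if (any(!is.finite(m)) || any(m < 0 | m > 100))
    stop("item scores must lie in [0, 100]")
  data.frame(item = seq_len(16),
             mean_score = colMeans(m),
             n_zero = colSums(m == 0),
             n_full = colSums(m == 100))
}
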