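#' @title Signal files, run configuration and end-to-end orchestration
#' @description Plain-text signal format (delimited samples plus a JSON
#'   metadata sidecar), a nested run configuration, and the four-stage
#'   pipeline: pre-process, extract features, vote-select, train/evaluate --
#'   run independently for the two classification scenarios (baseline vs
#'   VNS at 10 Hz; baseline vs VNS at 30 Hz).
#' @name pipeline
NULL

#' Write a recording as delimited text plus a JSON sidecar
#'
#' The signal file has two columns (`time_s`, `amplitude_uv`); the sidecar
#' (`<path>.json`) carries `fs_hz` and the metadata fields.
#'
#' @param recording an [egg_recording()].
#' @param path path of the signal file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "egg_recording"))
  n <- length(recording$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$fs_hz,
                   amplitude_uv = recording$samples)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- recording[c("fs_hz", "subject_id", "session_id", "condition",
                      "stim_freq_hz", "channel_label")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Accepts a two-column (`time_s`, `amplitude_uv`) or single-column
#' (`amplitude_uv`) file. When a time column is present its implied rate
#' must agree with the sidecar's `fs_hz` to within 1e-6 relative.
#'
#' @param path path of the signal file (sidecar at `<path>.json`).
#' @return an [egg_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  required <- c("fs_hz", "subject_id", "session_id", "condition",
                "stim_freq_hz", "channel_label")
  missing_f <- setdiff(required, names(meta))
  if (length(missing_f))
    stop("sidecar missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  df <- utils::read.delim(path)
  samples <- if ("amplitude_uv" %in% names(df)) df$amplitude_uv else df[[1]]
  bad <- which(!is.finite(samples))
  if (length(bad))
    stop("non-finite samples at indices: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  if ("time_s" %in% names(df) && nrow(df) >= 2) {
    fs_file <- 1 / stats::median(diff(df$time_s))
    if (abs(fs_file - meta$fs_hz) > 1e-6 * meta$fs_hz)
      stop(sprintf("sidecar fs_hz (%g) inconsistent with time column (%g)",
                   meta$fs_hz, fs_file), call. = FALSE)
  }
  egg_recording(samples, meta$fs_hz, subject_id = meta$subject_id,
                session_id = meta$session_id, condition = meta$condition,
                stim_freq_hz = meta$stim_freq_hz,
                channel_label = meta$channel_label)
}

#' Run configuration for the end-to-end pipeline
#'
#' @param design a [study_design()] (simulate block) or `NULL` when
#'   `recordings` are supplied to [run_pipeline()] directly.
#' @param params a [generator_params()] template for simulation.
#' @param preprocess a [preprocess_config()].
#' @param features a [feature_config()].
#' @param selection_cutoff cumulative-weight cutoff for voting selection.
#' @param selector_methods_used base selectors to run.
#' @param model_name classifier for evaluation.
#' @param cv_folds folds for selection and evaluation.
#' @param test_fraction held-out fraction of the stratified split.
#' @param n_perm label permutations for the KS significance test.
#' @param include_removed_pct if `TRUE`, `removed_pct` enters the classifier
#'   feature set (default `FALSE`).
#' @param seed master seed.
#' @return object of class `egg_run_config`.
#' @export
run_config <- function(design = study_design(),
                       params = generator_params(),
                       preprocess = preprocess_config(),
                       features = feature_config(),
                       selection_cutoff = 0.9,
                       selector_methods_used = selector_methods(),
                       model_name = "random_forest",
                       cv_folds = 5L,
                       test_fraction = 0.2,
                       n_perm = 1000L,
                       include_removed_pct = FALSE,
                       seed = 1L) {
  structure(as.list(environment()), class = "egg_run_config")
}

# classifier input columns for a feature table
.model_columns <- function(config) {
  cols <- feature_names()
  if (isTRUE(config$include_removed_pct)) cols <- c(cols, "removed_pct")
  cols
}

#' Run one classification scenario
#'
#' Pre-processes the scenario's recordings, extracts features, runs the
#' voting selection, then evaluates the classifier on the selected features:
#' a stratified 80/20 split, unshuffled stratified k-fold CV on the training
#' portion, and the label-permutation KS test.
#'
#' @param recordings list of [egg_recording()]s belonging to one scenario
#'   (one stimulation frequency plus its baselines).
#' @param config an [run_config()].
#' @return list with `features` (table), `selection` (`egg_voting_result`),
#'   `cv` (`egg_cv_result` on the training split), `permutation`
#'   (`egg_permutation_test`), and `counts` (per-stage bookkeeping).
#' @export
run_scenario <- function(recordings, config = run_config()) {
  windows <- list()
  excised <- substituted <- n_raw <- n_drop <- 0L
  for (rec in recordings) {
    w <- preprocess_recording(rec, config$preprocess)
    excised <- excised + attr(w, "excised_count")
    substituted <- substituted + attr(w, "substituted_count")
    n_raw <- n_raw + attr(w, "n_windows_raw")
    n_drop <- n_drop + attr(w, "n_windows_dropped")
    windows <- c(windows, w)
  }
  if (length(windows) == 0)
    stop("no usable windows after the removed-pct filter", call. = FALSE)
  tab <- feature_table(windows, config$features)
  y <- factor(tab$label, levels = c("baseline", "vns"))
  X <- tab[, .model_columns(config), drop = FALSE]

  voting <- select_features(X, y, methods = config$selector_methods_used,
                            cutoff = config$selection_cutoff,
                            cv_folds = config$cv_folds,
                            seed = .sub_seed(config$seed, 31))
  split <- stratified_split(y, config$test_fraction,
                            seed = .sub_seed(config$seed, 32))
  X_sel <- X[, voting$selected, drop = FALSE]
  cv <- cross_validate(config$model_name, X_sel[split$train, , drop = FALSE],
                       y[split$train], k = config$cv_folds,
                       seed = .sub_seed(config$seed, 33))
  perm <- permutation_ks_test(config$model_name,
                              X_sel[split$train, , drop = FALSE],
                              y[split$train], k = config$cv_folds,
                              n_perm = config$n_perm,
                              seed = .sub_seed(config$seed, 34))
  list(features = tab, selection = voting, cv = cv, permutation = perm,
       counts = list(excised = excised, substituted = substituted,
                     windows_raw = n_raw, windows_dropped = n_drop,
                     windows_kept = length(windows)))
}

#' Run the full pipeline and write artifacts
#'
#' Simulates (or ingests) a study, then runs each scenario present in the
#' data. Writes per-scenario feature tables (TSV), selection and evaluation
#' reports (JSON), and a run manifest with the configuration hash, seed and
#' stage counts.
#'
#' @param config an [run_config()].
#' @param out_dir output directory (created if absent).
#' @param recordings optional list of [egg_recording()]s; when `NULL` the
#'   config's simulate block generates them.
#' @return invisibly, a named list of scenario results plus `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir, recordings = NULL) {
  stopifnot(inherits(config, "egg_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(recordings)) {
    design <- config$design
    design$seed <- config$seed
    recordings <- generate_study(design, config$params)
  }
  stim_present <- sort(unique(vapply(recordings, `[[`, 0, "stim_freq_hz")))
  stim_present <- stim_present[stim_present > 0]
  if (length(stim_present) == 0)
    stop("no VNS recordings: nothing to classify", call. = FALSE)

  cfg_for_hash <- unclass(config)
  cfg_hash <- rlang::hash(lapply(cfg_for_hash, unclass))
  results <- list()
  for (f in stim_present) {
    scen_name <- sprintf("baseline_vs_vns%02dhz", as.integer(f))
    # a scenario = that frequency's sessions: their baseline + VNS recordings
    sess <- unique(vapply(Filter(function(r) r$stim_freq_hz == f, recordings),
                          `[[`, "", "session_id"))
    recs <- Filter(function(r) r$session_id %in% sess, recordings)
    res <- run_scenario(recs, config)
    results[[scen_name]] <- res

    write_feature_table(res$features,
                        file.path(out_dir, paste0(scen_name, "_features.tsv")))
    jsonlite::write_json(
      list(config_hash = cfg_hash,
           avg_weights = as.list(res$selection$avg_weights),
           ranked_features = res$selection$ranked_features,
           selected = res$selection$selected,
           cutoff = res$selection$cumulative_cutoff),
      file.path(out_dir, paste0(scen_name, "_selection.json")),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(config_hash = cfg_hash,
           model = config$model_name,
           fold_auc = res$cv$fold_auc,
           fold_accuracy = res$cv$fold_accuracy,
           fold_f1 = res$cv$fold_f1,
           fold_f2 = res$cv$fold_f2,
           ks_statistic = res$permutation$ks_statistic,
           ks_p_value = res$permutation$p_value,
           observed_aucs = res$permutation$observed_aucs,
           null_auc_mean = mean(res$permutation$null_aucs)),
      file.path(out_dir, paste0(scen_name, "_evaluation.json")),
      auto_unbox = TRUE, digits = NA)
  }
  manifest <- list(
    config_hash = cfg_hash, seed = config$seed,
    scenarios = names(results),
    counts = lapply(results, `[[`, "counts"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}

#' Headline separability experiment
#'
#' Runs the strong-amplitude-effect simulation end to end: a seeded study of
#' 7 subjects with 10-minute baseline and VNS-10Hz segments, pre-processing,
#' feature extraction, voting feature selection, a stratified 80/20 split,
#' unshuffled stratified 5-fold cross-validation of a random forest on the
#' training portion, and the label-permutation KS significance test of the
#' fold AUCs against the pooled permutation null.
#'
#' @param seed master seed for generation, selection, splitting and the
#'   permutation test.
#' @param n_perm number of label permutations (default 1000).
#' @param fs_hz sampling rate of the simulated recordings (default 2000).
#' @param n_subjects number of simulated subjects (default 7).
#' @return list with `ks_statistic`, `p_value`, `observed_aucs`,
#'   `null_aucs`, `selected`, `n_windows`.
#' @export
run_headline_separability <- function(seed = 1L, n_perm = 1000L,
                                      fs_hz = 2000, n_subjects = 7L) {
  design <- study_design(n_subjects = n_subjects, stim_freqs_hz = 10,
                         segment_duration_s = 600, fs_hz = fs_hz,
                         seed = seed)
  recs <- generate_study(design)
  windows <- list()
  for (r in recs) windows <- c(windows, preprocess_recording(r))
  tab <- feature_table(windows)
  y <- factor(tab$label, levels = c("baseline", "vns"))
  X <- tab[, feature_names()]
  voting <- select_features(X, y, seed = .sub_seed(seed, 31))
  split <- stratified_split(y, 0.2, seed = .sub_seed(seed, 32))
  X_sel <- X[split$train, voting$selected, drop = FALSE]
  pt <- permutation_ks_test("random_forest", X_sel, y[split$train],
                            n_perm = n_perm, seed = .sub_seed(seed, 33))
  list(ks_statistic = pt$ks_statistic, p_value = pt$p_value,
       observed_aucs = pt$observed_aucs, null_aucs = pt$null_aucs,
       selected = voting$selected, n_windows = nrow(tab))
}
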