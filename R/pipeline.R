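#' End-to-end pipeline
#'
#' Orchestrates simulate -> preprocess -> features -> statistics ->
#' importance -> consensus -> latency with one master seed, optional stage
#' toggles, and persisted intermediates.
#'
#' @name pipeline
NULL

#' Build a pipeline run configuration
#'
#' @param generator a [generator_config()]; the default reproduces the study
#'   design (20 subjects x 5 stages).
#' @param bandpass list with `low`, `high` (Hz) and `order`; set to `NULL`
#'   to skip filtering.
#' @param features list with `window_s` and band-isolation `method`; `NULL`
#'   skips feature extraction (and with it the statistics stage).
#' @param stats list with `feature`, `alpha` and `assumption_alpha`.
#' @param importance `NULL` to disable, else list with `stages`,
#'   `model_kind`, `span_ms`, `width_ms`, `count`, `n_shap`, `topk`,
#'   `max_rows`.
#' @param latency `NULL` to disable, else list with `channels` (`NULL`
#'   means: use the consensus set, falling back to the top importance
#'   channel), `band`, `k`, `consec_stft`, `consec_ae`, `window_ms`,
#'   `epochs`, `hidden_dim`, `max_s`.
#' @param out_dir directory for persisted intermediates (`NULL`: keep in
#'   memory only).
#' @param seed master seed; all module substreams derive from it.
#' @return a `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       bandpass = list(low = 0.1, high = 30, order = 10L),
                       features = list(window_s = 1, method = "fft"),
                       stats = list(feature = "pr_alpha", alpha = 0.05,
                                    assumption_alpha = 0.05),
                       importance = list(stages = NULL, model_kind = "rf",
                                         span_ms = 5000, width_ms = 500,
                                         count = 100L, n_shap = 64L,
                                         topk = 5L, max_rows = 40L),
                       latency = list(channels = NULL, band = "alpha",
                                      k = 3, consec_stft = 2L,
                                      consec_ae = 2L, window_ms = 50,
                                      epochs = 200L, hidden_dim = 8L,
                                      max_s = 10),
                       out_dir = NULL, seed = 1L) {
  structure(list(generator = generator, bandpass = bandpass,
                 features = features, stats = stats,
                 importance = importance, latency = latency,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Validate a run configuration
#'
#' Problems are returned, not thrown; an empty result means the
#' configuration satisfies all module invariants.
#'
#' @param config a [run_config()].
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character()
  gen <- try(validate_generator_config(config$generator), silent = TRUE)
  if (inherits(gen, "try-error"))
    problems <- c(problems, conditionMessage(attr(gen, "condition")))
  fs <- config$generator$fs
  if (!is.null(config$bandpass)) {
    bp <- config$bandpass
    if (!(bp$low > 0 && bp$low < bp$high))
      problems <- c(problems, "bandpass edges must satisfy 0 < low < high")
    if (bp$high >= fs / 2)
      problems <- c(problems,
                    sprintf("bandpass high edge %g Hz is at or above Nyquist (%g Hz)",
                            bp$high, fs / 2))
  }
  for (b in default_bands()) {
    if (b[2L] >= fs / 2)
      problems <- c(problems,
                    sprintf("analysis band reaching %g Hz is at or above Nyquist (%g Hz)",
                            b[2L], fs / 2))
  }
  if (is.na(config$seed) || config$seed < 0)
    problems <- c(problems, "seed must be a non-negative integer")
  if (!is.null(config$out_dir) && !dir.exists(dirname(config$out_dir)))
    problems <- c(problems, paste0("parent of out_dir does not exist: ",
                                   config$out_dir))
  problems
}

config_fingerprint <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "out_dir")]),
             collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(paste(s, collapse = ""))) %% 97 + 1)) %% .Machine$integer.max)
}

write_csv_with_provenance <- function(df, path, fingerprint, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# thermoeeg intermediate; seed=%d config=%s",
                     seed, fingerprint), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, then runs the enabled stages in order:
#' preprocessing, windowed feature extraction, the condition-pooling check
#' and per-channel stage battery, classifier + Shapley importance with the
#' statistical/importance consensus, and both latency estimators on
#' onset-bearing segments. Reruns with identical configuration and seed
#' reproduce the identical report.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pregenerated `list(segments, ground_truth)`
#'   matching the configuration; by default the cohort is simulated.
#' @return a `run_report` with per-stage row counts, assumption reports,
#'   significant and consensus channel sets, latency summaries and the
#'   configuration fingerprint.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  problems <- validate_config(config)
  if (length(problems) > 0L)
    stop("invalid configuration: ", paste(problems, collapse = "; "))
  gen <- config$generator
  fingerprint <- config_fingerprint(config)
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  persist <- function(df, name) {
    if (!is.null(out_dir))
      write_csv_with_provenance(df, file.path(out_dir, name), fingerprint,
                                config$seed)
  }
  report <- list(seed = config$seed, fingerprint = fingerprint)

  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## simulate ---------------------------------------------------------------
  if (is.null(cohort)) cohort <- step("simulate", generate_cohort(gen))
  segments <- cohort$segments
  report$n_segments <- length(segments)
  report$n_subjects <- gen$n_subjects
  report$stages <- gen$stages

  ## preprocess -------------------------------------------------------------
  if (!is.null(config$bandpass)) {
    bp <- config$bandpass
    segments <- step("preprocess", lapply(segments, eeg_bandpass,
                                          low = bp$low, high = bp$high,
                                          order = bp$order))
  }

  ## features ---------------------------------------------------------------
  features <- NULL
  if (!is.null(config$features)) {
    features <- step("features", compute_feature_table(
      segments, window_s = config$features$window_s,
      method = config$features$method))
    report$n_feature_rows <- nrow(features)
    persist(features, "features.csv")
  }

  ## stats ------------------------------------------------------------------
  battery <- NULL
  if (!is.null(config$stats) && !is.null(features)) {
    pooling <- step("stats", pooling_check(features,
                                           alpha = config$stats$alpha))
    battery <- step("stats", channel_battery(
      features, feature = config$stats$feature,
      alpha = config$stats$alpha,
      assumption_alpha = config$stats$assumption_alpha))
    report$pooling <- pooling
    report$battery <- battery
    report$significant_channels <- significant_channels(battery)
    persist(battery, "stage_battery.csv")
  }

  ## importance + consensus ---------------------------------------------------
  consensus_sets <- list()
  if (!is.null(config$importance)) {
    imp_cfg <- config$importance
    stages <- imp_cfg$stages
    if (is.null(stages)) stages <- setdiff(gen$stages, gen$stages[1L])
    rows <- step("importance", cohort_window_features(
      segments, span_ms = imp_cfg$span_ms, width_ms = imp_cfg$width_ms,
      count = imp_cfg$count))
    importance <- list()
    for (st in stages) {
      fit <- step("importance", fit_stage_classifiers(
        rows, task = "ovr", stage = st, model_kind = imp_cfg$model_kind,
        seed = substream_seed(config$seed, 0L, match(st, gen$stages), 6L)))
      imp <- step("importance", shapley_importance(
        fit, rows[rows$stage == st, , drop = FALSE],
        n_samples = imp_cfg$n_shap, max_rows = imp_cfg$max_rows,
        seed = substream_seed(config$seed, 0L, match(st, gen$stages), 7L)))
      importance[[st]] <- imp
      if (!is.null(battery))
        consensus_sets[[st]] <- consensus(battery, imp, k = imp_cfg$topk)
    }
    report$importance <- importance
    report$consensus <- consensus_sets
    if (length(importance) > 0L)
      persist(do.call(rbind, lapply(names(importance), function(st)
        data.frame(stage = st, channel = names(importance[[st]]$scores),
                   shap = unname(importance[[st]]$scores)))),
        "importance.csv")
  }

  ## latency ----------------------------------------------------------------
  if (!is.null(config$latency)) {
    lat_cfg <- config$latency
    estimates <- list()
    for (st in names(gen$onset_spec)) {
      chs <- lat_cfg$channels
      if (is.null(chs)) {
        cs <- consensus_sets[[st]]
        chs <- if (!is.null(cs) && length(cs$intersection) > 0L)
          cs$intersection else if (!is.null(cs)) cs$importance[1L] else "C4"
      }
      chs <- intersect(chs, gen$channels)
      if (length(chs) == 0L) chs <- gen$channels[1L]
      for (i in seq_len(gen$n_subjects)) {
        nc_seg <- segments[[which(vapply(segments, function(s)
          s$subject == subject_label(i) && s$stage == gen$stages[1L],
          logical(1L)))[1L]]]
        post <- step("latency", generate_onset_segment(gen, i, st))
        bl <- step("latency", stft_baseline_stats(
          nc_seg, chs, band = lat_cfg$band))
        estimates[[length(estimates) + 1L]] <- step("latency", stft_latency(
          post, chs, bl, k = lat_cfg$k, consec = lat_cfg$consec_stft,
          max_s = lat_cfg$max_s))
        det <- step("latency", train_autoencoder(
          nc_seg, chs, window_ms = lat_cfg$window_ms,
          seed = substream_seed(config$seed, i, match(st, gen$stages), 8L),
          epochs = lat_cfg$epochs, hidden_dim = lat_cfg$hidden_dim,
          k = lat_cfg$k))
        estimates[[length(estimates) + 1L]] <- step("latency", anomaly_latency(
          det, post, consec = lat_cfg$consec_ae, max_s = lat_cfg$max_s))
      }
    }
    estimates <- do.call(rbind, estimates)
    report$latency_estimates <- estimates
    report$latency_summary <- suppressWarnings(latency_summary(estimates))
    persist(estimates, "latency.csv")
  }

  class(report) <- "run_report"
  if (!is.null(out_dir)) {
    sink <- file.path(out_dir, "consensus.json")
    if (length(consensus_sets) > 0L)
      jsonlite::write_json(lapply(consensus_sets, function(cs)
        list(statistical = cs$statistical, importance = cs$importance,
             intersection = cs$intersection)), sink, auto_unbox = FALSE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "config", x$fingerprint, "\n")
  cat("  segments processed:", x$n_segments, "(", x$n_subjects, "subjects x",
      length(x$stages), "stages )\n")
  if (!is.null(x$n_feature_rows))
    cat("  feature rows:", x$n_feature_rows, "\n")
  if (!is.null(x$pooling))
    cat("  poolable across conditions:", x$pooling$poolable, "\n")
  if (!is.null(x$significant_channels))
    cat("  significant channels:",
        paste(x$significant_channels, collapse = ", "), "\n")
  if (!is.null(x$consensus))
    for (st in names(x$consensus))
      cat("  consensus", st, ":",
          paste(x$consensus[[st]]$intersection, collapse = ", "), "\n")
  if (!is.null(x$latency_summary)) {
    cat("  latency summary:\n")
    print(x$latency_summary)
  }
  invisible(x)
}
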