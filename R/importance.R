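#' Stage-specific channel identification
#'
#' Classifiers over per-channel window features, Shapley-value channel
#' importance, and the consensus (set intersection) of statistically
#' significant channels with the top-ranked important channels.
#'
#' @name importance
NULL

#' Overlapping window features for classification
#'
#' Segments the first `span_ms` of a recording into `count` overlapping
#' windows of `width_ms` with evenly spaced start offsets
#' `start_i = round(i (span - width) / (count - 1))` samples, and extracts
#' the signed mean amplitude of every channel in every window (channels are
#' the feature axis).
#'
#' @param segment an [eeg_segment()].
#' @param span_ms analysed span from segment start (default 5000 ms).
#' @param width_ms window width (default 500 ms).
#' @param count number of windows (default 100).
#' @return data.frame with one row per window: one column per channel plus
#'   `subject`, `stage`, `window` and `start_s`.
#' @export
window_features <- function(segment, span_ms = 5000, width_ms = 500,
                            count = 100L) {
  stopifnot(inherits(segment, "eeg_segment"))
  if (count < 2L) stop("need at least 2 windows")
  fs <- segment$fs
  span <- round(span_ms / 1000 * fs)
  width <- round(width_ms / 1000 * fs)
  if (width > span) stop("window width exceeds the analysed span")
  if (span > ncol(segment$samples)) stop("span exceeds segment duration")
  starts <- round((seq_len(count) - 1L) * (span - width) / (count - 1L))
  feats <- vapply(starts, function(s0) {
    rowMeans(segment$samples[, (s0 + 1L):(s0 + width), drop = FALSE])
  }, numeric(nrow(segment$samples)))
  out <- as.data.frame(t(feats))
  names(out) <- segment$channel_labels
  out$subject <- segment$subject
  out$stage <- segment$stage
  out$window <- seq_len(count)
  out$start_s <- starts / fs
  out
}

#' @rdname window_features
#' @param segments list of segments; rows are stacked.
#' @export
cohort_window_features <- function(segments, span_ms = 5000, width_ms = 500,
                                   count = 100L) {
  do.call(rbind, lapply(segments, window_features, span_ms = span_ms,
                        width_ms = width_ms, count = count))
}

feature_columns <- function(rows) {
  setdiff(names(rows), c("subject", "stage", "window", "start_s"))
}

subject_folds <- function(subjects, k) {
  u <- unique(subjects)
  k <- min(k, length(u))
  split(u, rep_len(seq_len(k), length(u)))
}

fit_one <- function(x, y, model_kind, seed) {
  set.seed(seed)
  switch(model_kind,
    rf = randomForest::randomForest(x = x, y = y, ntree = 200L),
    svm = e1071::svm(x = x, y = y, kernel = "radial"),
    mlp = {
      df <- data.frame(x, .y = y, check.names = FALSE)
      nnet::nnet(.y ~ ., data = df, size = 8L, maxit = 300L, decay = 1e-3,
                 trace = FALSE, MaxNWts = 10000L)
    },
    stop("unknown model kind: ", model_kind))
}

predict_class <- function(model, model_kind, x) {
  switch(model_kind,
    rf = as.character(stats::predict(model, x)),
    svm = as.character(stats::predict(model, x)),
    mlp = {
      p <- stats::predict(model, as.data.frame(x), type = "raw")
      if (ncol(p) == 1L) {
        ifelse(p[, 1L] > 0.5, model$lev[2L], model$lev[1L])
      } else colnames(p)[max.col(p)]
    })
}

#' Fit stage classifiers with subject-grouped cross-validation
#'
#' Trains a multilayer perceptron, random forest or support-vector machine
#' to discriminate the five stages (multiclass) or one stage against the
#' rest (one-vs-rest) from per-channel window features. Cross-validation
#' folds group whole subjects so windows from one subject never appear on
#' both sides of a split; the final model is refit on all rows. Runs are
#' deterministic under a fixed seed. A fold whose training part lacks one of
#' the classes is an error.
#'
#' @param rows data.frame from [cohort_window_features()].
#' @param task `"multiclass"` (all stages) or `"ovr"` (one-vs-rest).
#' @param stage positive class, required for `task = "ovr"`.
#' @param model_kind `"rf"`, `"svm"` or `"mlp"`.
#' @param seed integer seed.
#' @param cv_folds number of subject-grouped folds.
#' @return a `stage_classifier` with the refit model, cross-validated
#'   `accuracy`, per-fold accuracies and an `acceptable` flag (accuracy at
#'   or above the 70% discrimination threshold).
#' @export
fit_stage_classifiers <- function(rows, task = c("multiclass", "ovr"),
                                  stage = NULL,
                                  model_kind = c("rf", "svm", "mlp"),
                                  seed = 1L, cv_folds = 5L) {
  task <- match.arg(task)
  model_kind <- match.arg(model_kind)
  fc <- feature_columns(rows)
  x <- as.matrix(rows[, fc, drop = FALSE])
  y <- if (task == "ovr") {
    if (is.null(stage)) stop("task 'ovr' needs a target stage")
    factor(ifelse(rows$stage == stage, stage, "rest"),
           levels = c("rest", stage))
  } else factor(rows$stage)
  if (nlevels(droplevels(y)) < 2L) stop("need at least 2 classes present")
  folds <- subject_folds(rows$subject, cv_folds)
  fold_acc <- numeric(length(folds))
  for (i in seq_along(folds)) {
    test_idx <- rows$subject %in% folds[[i]]
    ytr <- droplevels(y[!test_idx])
    if (nlevels(ytr) < nlevels(droplevels(y)))
      stop("class absent from training fold ", i)
    fit <- fit_one(x[!test_idx, , drop = FALSE], ytr, model_kind,
                   seed = seed + i)
    pred <- predict_class(fit, model_kind, x[test_idx, , drop = FALSE])
    fold_acc[i] <- mean(pred == as.character(y[test_idx]))
  }
  final <- fit_one(x, y, model_kind, seed = seed)
  structure(list(
    model = final, model_kind = model_kind, task = task, stage = stage,
    levels = levels(y), feature_names = fc,
    accuracy = mean(fold_acc), fold_accuracies = fold_acc,
    acceptable = mean(fold_acc) >= 0.70, seed = seed),
    class = "stage_classifier")
}

#' @export
print.stage_classifier <- function(x, ...) {
  cat(sprintf("<stage_classifier> %s/%s%s: CV accuracy %.3f (%s the 70%% threshold)\n",
              x$model_kind, x$task,
              if (!is.null(x$stage)) paste0("(", x$stage, ")") else "",
              x$accuracy, if (x$acceptable) "meets" else "below"))
  invisible(x)
}

## scalar prediction score of a fitted classifier on a feature matrix
predict_score <- function(fit, x, stage = NULL) {
  x <- as.matrix(x)
  colnames(x) <- fit$feature_names
  target <- if (!is.null(stage)) stage else
    if (fit$task == "ovr") fit$stage else stop("multiclass score needs a stage")
  switch(fit$model_kind,
    rf = {
      p <- stats::predict(fit$model, x, type = "prob")
      unname(p[, target])
    },
    mlp = {
      p <- stats::predict(fit$model, as.data.frame(x), type = "raw")
      if (ncol(p) == 1L) {
        unname(if (identical(target, fit$levels[2L])) p[, 1L] else 1 - p[, 1L])
      } else unname(p[, target])
    },
    svm = {
      if (fit$task != "ovr")
        stop("Shapley scores for SVM are supported for one-vs-rest fits")
      pr <- stats::predict(fit$model, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      sgn <- if (grepl(paste0("^", target, "/"), colnames(dv)[1L])) 1 else -1
      unname(sgn * dv[, 1L])
    })
}

#' Shapley-value channel importance
#'
#' Estimates per-channel Shapley values of the classifier score by
#' permutation sampling against a background point (the marginal feature
#' means of the training rows). For each sampled permutation, features are
#' switched one by one from the background to the explained row and the
#' score increments are accredited to the switched channel; the estimator is
#' unbiased in the sampling limit and satisfies the efficiency property
#' (per-row attributions sum to score minus background score) exactly for
#' every sampled permutation set.
#'
#' @param fit a [fit_stage_classifiers()] result.
#' @param rows data.frame of window-feature rows used for the explanation.
#' @param stage class whose score is attributed (defaults to the fit's
#'   positive class).
#' @param n_samples number of sampled permutations (at least 1).
#' @param seed integer seed.
#' @param max_rows maximum number of rows to explain (sampled
#'   deterministically).
#' @return an `importance_result`: named mean-absolute Shapley `scores`,
#'   the channel `ranking`, the per-row attribution matrix `phi`, the
#'   explained scores and background score, and the fit's accuracy.
#' @export
shapley_importance <- function(fit, rows, stage = NULL, n_samples = 256L,
                               seed = 1L, max_rows = 50L) {
  if (n_samples < 1L) stop("n_samples must be at least 1")
  fc <- fit$feature_names
  X <- as.matrix(rows[, fc, drop = FALSE])
  set.seed(seed)
  if (nrow(X) > max_rows) X <- X[sample(nrow(X), max_rows), , drop = FALSE]
  p <- ncol(X); nr <- nrow(X)
  bg <- colMeans(as.matrix(rows[, fc, drop = FALSE]))
  phi <- matrix(0, nr, p, dimnames = list(NULL, fc))
  for (s in seq_len(n_samples)) {
    perm <- sample.int(p)
    # stack the p+1 cumulative states for all rows into one prediction batch
    states <- matrix(rep(bg, each = nr * (p + 1L)), nrow = nr * (p + 1L))
    for (j in seq_len(p)) {
      rows_j <- (j * nr + 1L):((p + 1L) * nr)        # states j..p
      cols <- perm[j]
      states[rows_j, cols] <- rep(X[, cols], p - j + 1L)
    }
    sc <- predict_score(fit, states, stage = stage)
    sc <- matrix(sc, nrow = nr)                       # rows x (p+1) states
    inc <- sc[, -1L, drop = FALSE] - sc[, -(p + 1L), drop = FALSE]
    phi[, perm] <- phi[, perm] + inc
  }
  phi <- phi / n_samples
  scores <- colMeans(abs(phi))
  base_score <- predict_score(fit, matrix(bg, 1L, p), stage = stage)
  structure(list(
    stage = if (!is.null(stage)) stage else fit$stage,
    scores = scores,
    ranking = names(sort(scores, decreasing = TRUE)),
    phi = phi,
    row_scores = predict_score(fit, X, stage = stage),
    background_score = as.numeric(base_score),
    accuracy = fit$accuracy, model_kind = fit$model_kind,
    n_samples = n_samples), class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat("<importance_result> stage", x$stage, "- top channels:",
      paste(utils::head(x$ranking, 5L), collapse = ", "), "\n")
  invisible(x)
}

#' Consensus of statistical and importance-based channel sets
#'
#' Intersects the FDR-significant channel set with the top-`k` channels by
#' Shapley importance for a stage; overlapping channels are the
#' high-confidence targets for temporal analysis.
#'
#' @param stat_set character vector of statistically significant channels
#'   (or a [channel_battery()] result).
#' @param importance_result an [shapley_importance()] result, or a character
#'   vector already ordered by decreasing importance.
#' @param k number of top importance channels to intersect.
#' @param montage optional [montage()] extending the channel universe used
#'   for the disjoint-montage check.
#' @return a `consensus_set` with `statistical`, `importance` (top-k) and
#'   `intersection`.
#' @export
consensus <- function(stat_set, importance_result, k = 5L, montage = NULL) {
  if (inherits(stat_set, "stage_stats")) stat_set <- significant_channels(stat_set)
  ranking <- if (inherits(importance_result, "importance_result"))
    importance_result$ranking else as.character(importance_result)
  stage <- if (inherits(importance_result, "importance_result"))
    importance_result$stage else NA_character_
  # the two analyses must speak about one montage: compare channel universes
  # (all scored channels, not the top-k, whose overlap may legitimately be empty)
  universe <- if (inherits(importance_result, "importance_result"))
    names(importance_result$scores) else ranking
  if (!is.null(montage)) universe <- union(universe, montage$labels)
  if (length(stat_set) > 0L && length(intersect(stat_set, universe)) == 0L)
    stop("statistical and importance channel sets come from disjoint montages")
  topk <- utils::head(ranking, k)
  structure(list(stage = stage, statistical = stat_set, importance = topk,
                 intersection = intersect(topk, stat_set)),
            class = "consensus_set")
}

#' @export
print.consensus_set <- function(x, ...) {
  cat("<consensus_set>", if (!is.na(x$stage)) paste0("stage ", x$stage) else "",
      "\n  statistical:", paste(x$statistical, collapse = ", "),
      "\n  importance :", paste(x$importance, collapse = ", "),
      "\n  consensus  :", paste(x$intersection, collapse = ", "), "\n")
  invisible(x)
}
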