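#' Response-latency estimation
#'
#' Two per-subject onset estimators: (i) short-time Fourier band-power
#' deviation from a baseline-calibrated threshold, and (ii) reconstruction
#' error of a participant-specific autoencoder trained only on baseline
#' windows. Both statistics are thresholded on the log scale: the log of a
#' band power (or of a mean-square reconstruction error) estimated from a
#' short window is far closer to Gaussian than the raw, chi-squared-like
#' quantity, so a mean + k SD rule holds its nominal Gaussian false-alarm
#' bound.
#'
#' @name latency
NULL

#' Short-time Fourier transform of one channel
#'
#' Hanning-tapered sliding periodograms; the frequency axis is truncated at
#' `max_freq` (30 Hz by default, the analysed EEG range).
#'
#' @param segment an [eeg_segment()] or numeric vector.
#' @param channel channel label (ignored for bare vectors).
#' @param window_ms taper length in milliseconds (500 by default).
#' @param overlap_fraction fractional overlap between consecutive windows
#'   (0.5 by default).
#' @param fs sampling rate for bare vectors.
#' @param max_freq highest retained frequency (Hz).
#' @return a `spectrogram_grid`: `time` (window centres, s), `freq` (Hz),
#'   `power` (freq x time, microvolts squared per Hz) and the window
#'   geometry.
#' @export
stft <- function(segment, channel = NULL, window_ms = 500,
                 overlap_fraction = 0.5, fs = NULL, max_freq = 30) {
  if (inherits(segment, "eeg_segment")) {
    if (is.null(channel)) stop("channel required for an eeg_segment")
    x <- segment$samples[channel, ]
    fs <- segment$fs
  } else {
    x <- as.numeric(segment)
    if (is.null(fs)) stop("fs required for bare vectors")
  }
  nwin <- round(window_ms / 1000 * fs)
  if (nwin > length(x)) stop("window longer than segment")
  hop <- max(1L, round(nwin * (1 - overlap_fraction)))
  starts <- seq(1L, length(x) - nwin + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nwin - 1) / (nwin - 1))  # Hanning
  U <- sum(w^2)
  K <- floor(nwin / 2)
  f <- (0:K) * fs / nwin
  keep <- f <= max_freq
  pow <- vapply(starts, function(s0) {
    X <- stats::fft(x[s0:(s0 + nwin - 1L)] * w)
    P <- Mod(X[1:(K + 1L)])^2 / (fs * U)
    P[-c(1L, if (nwin %% 2 == 0) K + 1L else integer())] <-
      2 * P[-c(1L, if (nwin %% 2 == 0) K + 1L else integer())]
    P[keep]
  }, numeric(sum(keep)))
  structure(list(time = (starts - 1L + nwin / 2) / fs,
                 start_s = (starts - 1L) / fs,
                 freq = f[keep], power = pow,
                 window_s = nwin / fs, hop_s = hop / fs, fs = fs),
            class = "spectrogram_grid")
}

## band power (uV^2) per STFT frame by integrating the PSD over (low, high]
grid_band_power <- function(grid, band) {
  if (is.character(band)) band <- default_bands()[[band]]
  df <- grid$freq[2L] - grid$freq[1L]
  idx <- which(grid$freq > band[1L] & grid$freq <= band[2L])
  if (length(idx) == 0L) stop("band contains no spectrogram bins")
  colSums(grid$power[idx, , drop = FALSE]) * df
}

## per-frame log band power, averaged over a channel set: single-channel
## frame power has chi-squared-like noise (few degrees of freedom in a
## 0.5-s window); averaging the log power across the analysed channel set
## shrinks the frame SD so a mean + 3 SD rule can resolve realistic effects
frame_log_band_power <- function(segment, channels, band, window_ms,
                                 overlap_fraction) {
  lp <- NULL
  for (ch in channels) {
    g <- stft(segment, ch, window_ms, overlap_fraction)
    v <- log(grid_band_power(g, band))
    lp <- if (is.null(lp)) v else lp + v
  }
  list(lp = lp / length(channels), grid = g)
}

#' Baseline statistics for the STFT detector
#'
#' Mean and SD of the log band power over the frames of a baseline (NC)
#' recording of the same subject, averaged across the analysed channel set.
#'
#' @param baseline_segment baseline [eeg_segment()].
#' @inheritParams stft
#' @param channels channel label(s); with several channels the per-frame
#'   log band powers are averaged across channels before the statistics are
#'   taken (the detection statistic must be computed the same way).
#' @param band analysed band (name or `c(low, high)`), alpha by default.
#' @return list with `mean`, `sd` (log scale), the channel set and the
#'   frame geometry.
#' @export
stft_baseline_stats <- function(baseline_segment, channels,
                                band = "alpha", window_ms = 500,
                                overlap_fraction = 0.5) {
  fl <- frame_log_band_power(baseline_segment, channels, band, window_ms,
                             overlap_fraction)
  if (length(fl$lp) < 8L) stop("baseline too short: need at least 8 frames")
  list(mean = mean(fl$lp), sd = stats::sd(fl$lp), channels = channels,
       window_ms = window_ms, overlap_fraction = overlap_fraction,
       band = band)
}

latency_estimate <- function(subject, stage, method, onset_s, detected,
                             channels = NA_character_) {
  data.frame(subject = subject, stage = stage, method = method,
             onset_s = onset_s, detected = detected,
             channels = paste(channels, collapse = "+"))
}

#' STFT band-power deviation latency
#'
#' Onset is the start time of the first run of `consec` frames whose log
#' band power deviates from the baseline mean by more than `k` baseline SDs
#' (in either direction; cold exposure suppresses alpha, injected responses
#' may raise it). Returns a non-detection when no such run occurs within
#' `max_s` of the segment start.
#'
#' @param segment post-transition [eeg_segment()].
#' @param channels analysed channel(s); must match the baseline statistics.
#' @param baseline_stats from [stft_baseline_stats()]; baseline frames of
#'   the same subject and channel set are required.
#' @param band analysed band (defaults to the baseline's band).
#' @param k threshold in baseline SD units (default 3).
#' @param consec required number of consecutive deviant frames (default 2).
#' @param max_s search horizon in seconds (default 10).
#' @return a one-row latency estimate data.frame (`onset_s` is `NA` when
#'   nothing is detected).
#' @export
stft_latency <- function(segment, channels = NULL, baseline_stats = NULL,
                         band = NULL, k = 3, consec = 2L, max_s = 10) {
  if (is.null(baseline_stats) || is.null(baseline_stats$mean))
    stop("missing baseline statistics")
  if (is.null(channels)) channels <- baseline_stats$channels
  band <- if (is.null(band)) baseline_stats$band else band
  fl <- frame_log_band_power(segment, channels, band,
                             baseline_stats$window_ms,
                             baseline_stats$overlap_fraction)
  dev <- abs(fl$lp - baseline_stats$mean) > k * baseline_stats$sd
  dev[fl$grid$start_s > max_s] <- FALSE
  onset <- NA_real_
  run <- 0L
  for (i in seq_along(dev)) {
    run <- if (dev[i]) run + 1L else 0L
    if (run >= consec) { onset <- fl$grid$start_s[i - consec + 1L]; break }
  }
  latency_estimate(segment$subject, segment$stage, "stft", onset,
                   !is.na(onset), channels)
}

## ---- autoencoder ----------------------------------------------------------

## non-overlapping windows of one channel: samples matrix (d x n_windows);
## each window is centred on its own mean (the DC offset of a 50-ms EEG
## window is dominated by slow drift whose autocorrelation spans several
## windows and would otherwise cluster reconstruction-error exceedances)
ae_windows <- function(x, fs, window_ms, center = TRUE) {
  d <- floor(window_ms / 1000 * fs)
  n_win <- floor(length(x) / d)
  if (n_win < 1L) stop("signal shorter than one window")
  m <- matrix(x[seq_len(d * n_win)], nrow = d)
  if (center) m <- m - rep(colMeans(m), each = d)
  m
}

ae_init <- function(d, h, seed) {
  set.seed(seed)
  list(W1 = matrix(stats::rnorm(h * d, 0, 0.3 / sqrt(d)), h, d),
       b1 = numeric(h),
       W2 = matrix(stats::rnorm(d * h, 0, 0.3 / sqrt(h)), d, h),
       b2 = numeric(d))
}

ae_forward <- function(par, X) {
  # X: d x n
  Z <- tanh(par$W1 %*% X + par$b1)
  Xhat <- par$W2 %*% Z + par$b2
  list(Z = Z, Xhat = Xhat)
}

ae_loss <- function(par, X) {
  fw <- ae_forward(par, X)
  mean((fw$Xhat - X)^2)
}

ae_grad <- function(par, X) {
  n <- ncol(X); d <- nrow(X)
  fw <- ae_forward(par, X)
  E <- 2 * (fw$Xhat - X) / (n * d)        # dL/dXhat
  gW2 <- E %*% t(fw$Z)
  gb2 <- rowSums(E)
  dZ <- (t(par$W2) %*% E) * (1 - fw$Z^2)
  gW1 <- dZ %*% t(X)
  gb1 <- rowSums(dZ)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

## full-batch gradient descent with backtracking: the recorded epoch losses
## are non-increasing by construction
ae_train <- function(X, hidden_dim, epochs, seed, lr = 0.5) {
  par <- ae_init(nrow(X), hidden_dim, seed)
  losses <- numeric(epochs + 1L)
  losses[1L] <- ae_loss(par, X)
  for (e in seq_len(epochs)) {
    g <- ae_grad(par, X)
    repeat {
      cand <- list(W1 = par$W1 - lr * g$W1, b1 = par$b1 - lr * g$b1,
                   W2 = par$W2 - lr * g$W2, b2 = par$b2 - lr * g$b2)
      l_new <- ae_loss(cand, X)
      if (l_new <= losses[e] || lr < 1e-10) break
      lr <- lr / 2
    }
    if (l_new <= losses[e]) {
      par <- cand
      losses[e + 1L] <- l_new
      lr <- lr * 1.1
    } else {
      losses[e + 1L] <- losses[e]
    }
  }
  list(par = par, losses = losses)
}

#' Train a participant-specific baseline autoencoder
#'
#' One single-hidden-layer autoencoder (tanh encoder, linear decoder) per
#' requested channel, trained exclusively on non-overlapping baseline
#' windows (50 ms by default; at 1024 Hz the window is floored to 51
#' samples and advanced by exactly 51 samples, so windows stay
#' non-overlapping at the cost of a 0.2 sample/window drift). Inputs are
#' z-normalized with per-channel baseline constants. A held-out fraction of
#' baseline windows calibrates the detection threshold
#' `mean + k SD` of the log reconstruction error (averaged across channels).
#'
#' @param baseline_segment baseline (NC) [eeg_segment()].
#' @param channels channels to model (the consensus set in the pipeline).
#' @param window_ms window length in milliseconds.
#' @param seed integer seed (weight initialization and the holdout split).
#' @param epochs gradient-descent epochs.
#' @param hidden_dim hidden-layer width.
#' @param k threshold in held-out SD units.
#' @param holdout_frac fraction of baseline windows held out for
#'   calibration.
#' @param min_windows required minimum number of baseline windows.
#' @return an `anomaly_detector` with per-channel weights and normalization
#'   constants, epoch losses, baseline log-error statistics (training and
#'   held-out) and the threshold.
#' @export
train_autoencoder <- function(baseline_segment, channels, window_ms = 50,
                              seed = 1L, epochs = 200L, hidden_dim = 8L,
                              k = 3, holdout_frac = 0.25,
                              min_windows = 200L) {
  stopifnot(inherits(baseline_segment, "eeg_segment"))
  missing <- setdiff(channels, baseline_segment$channel_labels)
  if (length(missing) > 0L)
    stop("baseline segment lacks channels: ", paste(missing, collapse = ", "))
  fs <- baseline_segment$fs
  per_ch <- list()
  n_win <- NULL
  for (ch in channels) {
    X <- ae_windows(baseline_segment$samples[ch, ], fs, window_ms)
    if (ncol(X) < min_windows)
      stop("need at least ", min_windows, " baseline windows, got ", ncol(X))
    n_win <- ncol(X)
    mu <- mean(X); sdv <- stats::sd(as.numeric(X))
    per_ch[[ch]] <- list(X = (X - mu) / sdv, mu = mu, sd = sdv)
  }
  set.seed(substream_seed(seed, 0L, 0L, 4L))
  holdout <- sample(n_win, max(1L, round(holdout_frac * n_win)))
  train_idx <- setdiff(seq_len(n_win), holdout)
  err_train <- matrix(0, length(train_idx), length(channels))
  err_hold <- matrix(0, length(holdout), length(channels))
  for (i in seq_along(channels)) {
    ch <- channels[i]
    Xall <- per_ch[[ch]]$X
    fit <- ae_train(Xall[, train_idx, drop = FALSE], hidden_dim, epochs,
                    seed = substream_seed(seed, i, 0L, 5L))
    per_ch[[ch]]$par <- fit$par
    per_ch[[ch]]$losses <- fit$losses
    per_ch[[ch]]$X <- NULL
    rec_t <- ae_forward(fit$par, Xall[, train_idx, drop = FALSE])$Xhat
    rec_h <- ae_forward(fit$par, Xall[, holdout, drop = FALSE])$Xhat
    err_train[, i] <- colMeans((rec_t - Xall[, train_idx, drop = FALSE])^2)
    err_hold[, i] <- colMeans((rec_h - Xall[, holdout, drop = FALSE])^2)
  }
  le_train <- log(rowMeans(err_train))
  le_hold <- log(rowMeans(err_hold))
  structure(list(
    channels = channels, window_ms = window_ms, fs = fs,
    hidden_dim = hidden_dim, k = k, seed = seed,
    models = per_ch,
    log_err_train_mean = mean(le_train), log_err_train_sd = stats::sd(le_train),
    log_err_holdout_mean = mean(le_hold), log_err_holdout_sd = stats::sd(le_hold),
    log_err_holdout = le_hold,
    threshold = mean(le_hold) + k * stats::sd(le_hold)),
    class = "anomaly_detector")
}

#' @export
print.anomaly_detector <- function(x, ...) {
  cat(sprintf("<anomaly_detector> %d channel(s), %g-ms windows, hidden %d; log-error threshold %.3f (mean %.3f + %g sd)\n",
              length(x$channels), x$window_ms, x$hidden_dim, x$threshold,
              x$log_err_holdout_mean, x$k))
  invisible(x)
}

## per-window mean log reconstruction error of a post segment
detector_log_errors <- function(detector, segment) {
  missing <- setdiff(detector$channels, segment$channel_labels)
  if (length(missing) > 0L)
    stop("segment lacks detector channels: ", paste(missing, collapse = ", "))
  if (segment$fs != detector$fs)
    stop("sampling rate mismatch between detector and segment")
  errs <- NULL
  for (ch in detector$channels) {
    m <- detector$models[[ch]]
    X <- ae_windows(segment$samples[ch, ], segment$fs, detector$window_ms)
    Xn <- (X - m$mu) / m$sd
    rec <- ae_forward(m$par, Xn)$Xhat
    e <- colMeans((rec - Xn)^2)
    errs <- if (is.null(errs)) matrix(e, ncol = 1L) else cbind(errs, e)
  }
  log(rowMeans(errs))
}

#' Autoencoder reconstruction-error latency
#'
#' Windows of the post-transition segment are scored in order; the onset is
#' the start time of the first window (or first of `consec` consecutive
#' windows) whose log reconstruction error exceeds the detector threshold.
#' Returns a non-detection when nothing exceeds it within `max_s`.
#'
#' @param detector an [train_autoencoder()] result.
#' @param post_segment post-transition [eeg_segment()] covering the first
#'   seconds after the stage change.
#' @param consec consecutive windows required (default 2; the onset is
#'   still reported as the start of the first window of the run, so the
#'   estimate quantizes to the 50-ms grid, but a single-window rule cannot
#'   control the false-alarm rate over a 200-window scan).
#' @param threshold override of the detector's calibrated threshold (log
#'   scale); `Inf` disables detection.
#' @param max_s search horizon (default 10 s).
#' @return a one-row latency estimate data.frame.
#' @export
anomaly_latency <- function(detector, post_segment, consec = 2L,
                            threshold = NULL, max_s = 10) {
  le <- detector_log_errors(detector, post_segment)
  thr <- if (is.null(threshold)) detector$threshold else threshold
  win_s <- floor(detector$window_ms / 1000 * detector$fs) / detector$fs
  starts <- (seq_along(le) - 1L) * win_s
  exceed <- le > thr & starts <= max_s
  onset <- NA_real_
  run <- 0L
  for (i in seq_along(exceed)) {
    run <- if (exceed[i]) run + 1L else 0L
    if (run >= consec) { onset <- starts[i - consec + 1L]; break }
  }
  latency_estimate(post_segment$subject, post_segment$stage, "autoencoder",
                   onset, !is.na(onset), detector$channels)
}

#' Summarize latency estimates per stage
#'
#' Arithmetic mean and sample SD of the detected onsets per stage and
#' method; non-detections are counted separately and never imputed.
#'
#' @param estimates data.frame of latency estimates (rows from
#'   [stft_latency()] / [anomaly_latency()]).
#' @return data.frame with stage, method, n_detected, n_missing, mean and SD
#'   of the detected onsets.
#' @export
latency_summary <- function(estimates) {
  sp <- split(estimates, list(estimates$stage, estimates$method), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    det <- d$onset_s[d$detected]
    data.frame(stage = d$stage[1L], method = d$method[1L],
               n_detected = length(det), n_missing = sum(!d$detected),
               mean_onset_s = if (length(det) > 0L) mean(det) else NA_real_,
               sd_onset_s = if (length(det) > 1L) stats::sd(det) else
                 if (length(det) == 1L) 0 else NA_real_)
  }))
  rownames(out) <- NULL
  empty <- out$n_detected == 0L
  if (any(empty))
    warning("stages with no detected onsets: ",
            paste(unique(out$stage[empty]), collapse = ", "))
  out
}

#' Percent increase of one latency over a reference
#'
#' @param x estimated latency (s).
#' @param reference reference latency (s).
#' @return percent increase, `100 * (x - reference) / reference`.
#' @export
percent_increase <- function(x, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  100 * (x - reference) / reference
}
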