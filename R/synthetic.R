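#' Synthetic cold-exposure EEG cohorts
#'
#' The generator emulates the study design the analysis assumes: a cohort of
#' subjects, each recorded across the five thermal stages NC (thermoneutral
#' baseline), CE (cold exposure), WE (cold-wind stimulation), HB (habituation)
#' and PR (post-exposure recovery), under one of seven ambient
#' temperature/wind conditions.
#'
#' Each channel is synthesized as 1/f-shaped Gaussian noise, band-limited to
#' the canonical delta/theta/alpha/beta ranges, plus one narrowband
#' oscillation per band (a tone with random phase carrying a configurable
#' fraction of the band's power). Spectral amplitudes are drawn so that the
#' expected mean-square amplitude in each analysis band equals a configured
#' target exactly, which gives the test suite closed-form oracles: a stage
#' that multiplies the alpha-band amplitude by `m` multiplies the expected
#' alpha band power by exactly `m^2`.
#'
#' @name synthetic
NULL

STAGES <- c("NC", "CE", "WE", "HB", "PR")

# channels with a stage-dependent alpha response under the default effect spec
ALPHA_CHANNELS <- c("F8", "FC5", "FC2", "FC6", "Cz", "C4", "CP2",
                    "CP5", "CP6", "T7", "T8", "P4", "POz", "P7")

## deterministic substream derivation from one master seed:
## stream = (master * 48271 + subject*1009 + stage*101 + purpose*7) mod (2^31-19)
## (exact in double arithmetic; documented counter scheme)
substream_seed <- function(master, subject = 0L, stage = 0L, purpose = 0L) {
  m <- 2147483629
  s <- ((master %% m) * 48271 + subject * 1009 + stage * 101 + purpose * 7) %% m
  as.integer(max(1, s))
}

#' Generator configuration
#'
#' Defaults reproduce the study conditions: 20 subjects allocated 3/3/3/3/3/2/3
#' across seven ambient-temperature/wind conditions, five stages, 1024 Hz,
#' 120-s stage segments, a 30-channel montage, and stage-wise alpha-power
#' suppression on 14 designated channels with amplitude multipliers derived
#' from the reported stage-wise relative-alpha means (CE 0.74, WE 0.60,
#' HB 0.81, PR 0.74). True response onsets default to CE 0.5 s, WE 2 s,
#' PR 1 s.
#'
#' @param n_subjects number of subjects.
#' @param stages ordered stage labels; the first is the baseline.
#' @param conditions data.frame with columns `ambient_c`, `wind_ms`,
#'   `n_subjects`; the subject counts must sum to `n_subjects`.
#' @param fs sampling frequency in Hz.
#' @param duration_s seconds per stage segment.
#' @param channels montage labels.
#' @param effect_spec named list (per non-baseline stage) with elements
#'   `channels` (labels), `multiplier` (scalar, or named per-channel
#'   vector, alpha-band amplitude relative to baseline; power scales as the
#'   square) and optionally `offset_uv` (stage-dependent mean-amplitude
#'   shift in microvolts on the affected channels, default 0; windowed
#'   signed means are insensitive to band-power changes, so classifier
#'   recovery exercises this effect).
#' @param onset_spec named numeric vector of true response onsets (seconds,
#'   in `[0, 10)`) for stages with a defined transition.
#' @param onset_ramp_s length of the linear cross-fade at the onset; 0 gives
#'   an instantaneous parameter switch.
#' @param noise list controlling the spectral model: `exponent` (1/f slope),
#'   `total_power_uv2`, `rel_power` (named fractions for delta/theta/alpha/
#'   beta/gap summing to 1; "gap" is the 7-8 Hz range between theta and
#'   alpha), `osc_frac` (per-band fraction of power carried by the narrowband
#'   oscillation), `osc_freq` (oscillation frequencies, Hz),
#'   `tone_linewidth_hz` (Lorentzian linewidth of the phase-diffusing
#'   oscillations), `subject_sd` (log-normal between-subject spread of band
#'   powers), `white_noise_uv` (RMS of the flat measurement-noise floor,
#'   microvolts), `f_floor` (lowest synthesized frequency, Hz).
#' @param condition_offsets_uv per-condition DC offset in microvolts (default
#'   zero: condition affects physiology only, matching the pooled design).
#' @param physio_noise_sd measurement noise SD (deg C) for skin temperatures;
#'   also scales sensation noise.
#' @param seed master seed; all randomness is derived from it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_subjects = 20L,
                             stages = STAGES,
                             conditions = data.frame(
                               ambient_c = c(0, 0, -5, -10, -15, -20, -20),
                               wind_ms = c(7, 12, 12, 12, 12, 7, 12),
                               n_subjects = c(3L, 3L, 3L, 3L, 3L, 2L, 3L)),
                             fs = 1024,
                             duration_s = 120,
                             channels = default_montage()$labels,
                             effect_spec = list(
                               CE = list(channels = ALPHA_CHANNELS, multiplier = 0.74),
                               WE = list(channels = ALPHA_CHANNELS, multiplier = 0.60),
                               HB = list(channels = ALPHA_CHANNELS, multiplier = 0.81),
                               PR = list(channels = ALPHA_CHANNELS, multiplier = 0.74)),
                             onset_spec = c(CE = 0.5, WE = 2, PR = 1),
                             onset_ramp_s = 0,
                             noise = list(),
                             condition_offsets_uv = NULL,
                             physio_noise_sd = 0.3,
                             seed = 1L) {
  noise_defaults <- list(
    exponent = 1,
    total_power_uv2 = 100,
    rel_power = c(delta = 0.32, theta = 0.14, alpha = 0.40, beta = 0.12, gap = 0.02),
    osc_frac = c(delta = 0.2, theta = 0.3, alpha = 0.8, beta = 0.2, gap = 0),
    osc_freq = c(delta = 2, theta = 5.5, alpha = 10, beta = 20, gap = 7.5),
    tone_linewidth_hz = 0.15,
    subject_sd = 0.1,
    white_noise_uv = 2,
    f_floor = 0.5)
  noise <- utils::modifyList(noise_defaults, noise)
  if (is.null(condition_offsets_uv)) condition_offsets_uv <- rep(0, nrow(conditions))
  cfg <- structure(list(
    n_subjects = as.integer(n_subjects), stages = stages,
    conditions = conditions, fs = fs, duration_s = duration_s,
    channels = channels, effect_spec = effect_spec, onset_spec = onset_spec,
    onset_ramp_s = onset_ramp_s, noise = noise,
    condition_offsets_uv = condition_offsets_uv,
    physio_noise_sd = physio_noise_sd, seed = as.integer(seed)),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop("config error: n_subjects must be >= 1")
  if (cfg$fs <= 0) stop("config error: fs must be > 0")
  if (cfg$duration_s <= 0) stop("config error: duration_s must be > 0")
  if (anyDuplicated(cfg$stages)) stop("config error: stage labels must be unique")
  if (sum(cfg$conditions$n_subjects) != cfg$n_subjects)
    stop("config error: condition subject counts must sum to n_subjects")
  for (st in names(cfg$effect_spec)) {
    es <- cfg$effect_spec[[st]]
    if (any(es$multiplier <= 0))
      stop("config error: effect multipliers must be > 0")
    if (!all(es$channels %in% cfg$channels))
      stop("config error: effect channels outside the montage: ",
           paste(setdiff(es$channels, cfg$channels), collapse = ", "))
  }
  if (any(cfg$onset_spec < 0 | cfg$onset_spec >= 10))
    stop("config error: onsets must lie in [0, 10) seconds")
  if (abs(sum(cfg$noise$rel_power) - 1) > 1e-8)
    stop("config error: rel_power fractions must sum to 1")
  if (30 >= cfg$fs / 2)
    stop("config error: fs must exceed 60 Hz so the beta band is below Nyquist")
  invisible(cfg)
}

## synthesis bands: analysis bands plus the printed 7-8 Hz gap
synth_band_edges <- function(f_floor) {
  list(delta = c(f_floor, 4), theta = c(4, 7), gap = c(7, 8),
       alpha = c(8, 12), beta = c(12, 30))
}

## amplitude multiplier for a stage/channel under the effect spec
alpha_multiplier <- function(cfg, stage, channel) {
  es <- cfg$effect_spec[[stage]]
  if (is.null(es) || !(channel %in% es$channels)) return(1)
  m <- es$multiplier
  if (!is.null(names(m))) {
    if (channel %in% names(m)) unname(m[[channel]]) else 1
  } else m
}

## stage-dependent mean-amplitude shift (uV) for a stage/channel
stage_offset <- function(cfg, stage, channel) {
  es <- cfg$effect_spec[[stage]]
  if (is.null(es) || !(channel %in% es$channels) || is.null(es$offset_uv))
    return(0)
  o <- es$offset_uv
  if (!is.null(names(o))) {
    if (channel %in% names(o)) unname(o[[channel]]) else 0
  } else o
}

## per-subject per-band log-normal power factors (constant across stages)
subject_band_factors <- function(cfg, subject) {
  set.seed(substream_seed(cfg$seed, subject, 0L, 0L))
  f <- exp(stats::rnorm(5, 0, cfg$noise$subject_sd))
  names(f) <- c("delta", "theta", "gap", "alpha", "beta")
  f
}

## Synthesize one piece of signal with given per-band powers (uV^2).
## The RNG state is taken as-is; callers seed the substream.
synth_piece <- function(n, fs, band_powers, noise) {
  x <- numeric(n)
  if (n == 0L) return(x)
  K <- floor(n / 2)
  g2 <- numeric(K)                       # squared spectral gains
  f <- seq_len(K) * fs / n
  edges <- synth_band_edges(noise$f_floor)
  for (b in names(edges)) {
    P <- band_powers[[b]]
    Pn <- P * (1 - noise$osc_frac[[b]])
    idx <- which(f > edges[[b]][1] & f <= edges[[b]][2])
    if (length(idx) > 0L && Pn > 0) {
      w2 <- f[idx]^(-noise$exponent)
      g2[idx] <- Pn * n^2 / 2 * w2 / sum(w2)
    }
  }
  X <- complex(length.out = n)
  z <- matrix(stats::rnorm(2L * K), ncol = 2L)
  X[1L + seq_len(K)] <- sqrt(g2 / 2) * complex(real = z[, 1L], imaginary = z[, 2L])
  if (n %% 2 == 0 && K >= 1L) X[K + 1L] <- complex(real = sqrt(g2[K]) * z[K, 1L])
  n_conj <- n - K - 1L
  if (n_conj > 0L) X[n:(K + 2L)] <- Conj(X[seq(2L, length.out = n_conj)])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  t <- (seq_len(n) - 1L) / fs
  ## narrowband oscillations: constant amplitude, phase-diffusing carrier
  ## (random-walk phase with Lorentzian linewidth `tone_linewidth_hz`);
  ## the amplitude is deterministic, so frame-level band power is stable,
  ## while the phase decorrelates over ~1/linewidth seconds as real EEG
  ## rhythms do
  s_step <- sqrt(2 * pi * noise$tone_linewidth_hz / fs)
  for (b in names(edges)) {
    frac <- noise$osc_frac[[b]]
    if (frac > 0 && band_powers[[b]] > 0) {
      A <- sqrt(2 * frac * band_powers[[b]])
      theta <- stats::runif(1, 0, 2 * pi) +
        cumsum(stats::rnorm(n, 0, s_step))
      x <- x + A * cos(2 * pi * noise$osc_freq[[b]] * t + theta)
    }
  }
  ## flat measurement-noise floor (amplifier + residual artifact noise)
  if (noise$white_noise_uv > 0)
    x <- x + stats::rnorm(n, 0, noise$white_noise_uv)
  x
}

## band powers for one subject/stage/channel (uV^2 per synthesis band);
## subject_factors must be drawn beforehand so the segment RNG stream stays
## untouched inside channel loops
stage_band_powers <- function(cfg, stage, channel, subject_factors) {
  base <- cfg$noise$total_power_uv2 * cfg$noise$rel_power
  names(base) <- names(cfg$noise$rel_power)
  base <- base * subject_factors[names(base)]
  base[["alpha"]] <- base[["alpha"]] * alpha_multiplier(cfg, stage, channel)^2
  base
}

synth_segment_samples <- function(cfg, subject, stage, offset_uv) {
  n <- round(cfg$duration_s * cfg$fs)
  stage_idx <- match(stage, cfg$stages)
  sf <- subject_band_factors(cfg, subject)
  set.seed(substream_seed(cfg$seed, subject, stage_idx, 1L))
  samples <- matrix(0, nrow = length(cfg$channels), ncol = n,
                    dimnames = list(cfg$channels, NULL))
  for (ch in cfg$channels) {
    bp <- stage_band_powers(cfg, stage, ch, sf)
    samples[ch, ] <- synth_piece(n, cfg$fs, bp, cfg$noise) + offset_uv +
      stage_offset(cfg, stage, ch)
  }
  samples
}

#' EEG segment constructor
#'
#' @param samples channels x time numeric matrix (microvolts), rows named by
#'   channel label.
#' @param fs sampling frequency (Hz).
#' @param subject,stage,condition identifying labels.
#' @return an `eeg_segment`.
#' @export
eeg_segment <- function(samples, fs, subject = NA_character_,
                        stage = NA_character_, condition = NA_character_) {
  stopifnot(is.matrix(samples), !is.null(rownames(samples)))
  if (!all(is.finite(samples))) stop("segment samples must all be finite")
  structure(list(samples = samples, fs = fs,
                 channel_labels = rownames(samples),
                 subject = subject, stage = stage, condition = condition),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s/%s/%s: %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$subject, x$stage, x$condition, nrow(x$samples),
              ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  invisible(x)
}

subject_conditions <- function(cfg) {
  rep(seq_len(nrow(cfg$conditions)), cfg$conditions$n_subjects)
}

subject_label <- function(i) sprintf("S%02d", i)

#' Generate a synthetic cohort
#'
#' One segment per subject and stage (so the default design yields
#' 20 x 5 = 100 segments), with stage-dependent alpha suppression injected on
#' the configured channels. Identical configuration and seed give
#' bit-identical output.
#'
#' @param config a [generator_config()].
#' @return a list with `segments` (list of [eeg_segment()]) and
#'   `ground_truth` (class `synthetic_ground_truth`: affected channels and
#'   multipliers per stage, true onsets per subject/stage, and the seed).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  cond_of <- subject_conditions(config)
  segments <- vector("list", config$n_subjects * length(config$stages))
  k <- 0L
  for (i in seq_len(config$n_subjects)) {
    cond <- cond_of[i]
    off <- config$condition_offsets_uv[cond]
    for (stage in config$stages) {
      k <- k + 1L
      segments[[k]] <- eeg_segment(
        synth_segment_samples(config, i, stage, off),
        fs = config$fs, subject = subject_label(i), stage = stage,
        condition = paste0("C", cond))
    }
  }
  onsets <- matrix(NA_real_, nrow = config$n_subjects,
                   ncol = length(config$stages),
                   dimnames = list(subject_label(seq_len(config$n_subjects)),
                                   config$stages))
  for (st in names(config$onset_spec)) {
    if (st %in% config$stages) onsets[, st] <- config$onset_spec[[st]]
  }
  gt <- structure(list(
    affected_channels = lapply(config$effect_spec, `[[`, "channels"),
    alpha_multipliers = lapply(config$effect_spec, `[[`, "multiplier"),
    true_onsets_s = onsets,
    seed = config$seed), class = "synthetic_ground_truth")
  list(segments = segments, ground_truth = gt)
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat("<synthetic_ground_truth> stages with injected effects:",
      paste(names(x$affected_channels), collapse = ", "), "\n")
  invisible(x)
}

#' Expected band power implied by the generator
#'
#' Closed-form expectation of the mean-square amplitude in one analysis band
#' for a given stage/channel, marginal over segment realizations (the
#' between-subject log-normal factor is shared across stages, so stage/NC
#' ratios of the structured part are exact; the small flat noise floor adds
#' its in-band share). Used as the analytic oracle in recovery tests.
#'
#' @param config a [generator_config()].
#' @param stage,channel stage and channel labels.
#' @param band one of `"delta"`, `"theta"`, `"alpha"`, `"beta"`.
#' @return expected band power in microvolts squared.
#' @export
expected_band_power <- function(config, stage, channel, band) {
  band <- match.arg(band, c("delta", "theta", "alpha", "beta"))
  P <- config$noise$total_power_uv2 * config$noise$rel_power[[band]]
  P <- P * exp(config$noise$subject_sd^2 / 2)  # E[log-normal factor]
  if (band == "alpha") P <- P * alpha_multiplier(config, stage, channel)^2
  edges <- default_bands()[[band]]
  white <- config$noise$white_noise_uv^2 *
    (edges[2L] - max(edges[1L], 0)) / (config$fs / 2)
  P + white
}

#' Generate a segment with a response onset
#'
#' Samples before the true onset are drawn from the baseline (NC) spectral
#' parameters and samples after it from the stage parameters; the switch is
#' instantaneous (or a linear cross-fade of length `onset_ramp_s`), so the
#' true latency is unambiguous.
#'
#' @param config a [generator_config()].
#' @param subject subject index.
#' @param stage one of the stages named in `config$onset_spec`
#'   (CE, WE or PR by default).
#' @param onset_s optional override of the configured onset (seconds).
#' @return an [eeg_segment()] with attribute `"true_onset_s"`.
#' @export
generate_onset_segment <- function(config, subject, stage, onset_s = NULL) {
  validate_generator_config(config)
  if (!stage %in% names(config$onset_spec))
    stop("stage '", stage, "' has no configured onset (expected one of ",
         paste(names(config$onset_spec), collapse = ", "), ")")
  onset <- if (is.null(onset_s)) config$onset_spec[[stage]] else onset_s
  if (onset >= config$duration_s)
    stop("onset (", onset, " s) must precede the segment end (",
         config$duration_s, " s)")
  if (onset < 0) stop("onset must be >= 0")
  n <- round(config$duration_s * config$fs)
  stage_idx <- match(stage, config$stages)
  cond <- subject_conditions(config)[subject]
  off <- config$condition_offsets_uv[cond]
  samples <- matrix(0, nrow = length(config$channels), ncol = n,
                    dimnames = list(config$channels, NULL))
  n_pre <- round(onset * config$fs)
  ramp_n <- round(config$onset_ramp_s * config$fs)
  w <- c(rep(0, n_pre), pmin(1, if (ramp_n > 0) seq_len(n - n_pre) / ramp_n
                             else rep(1, n - n_pre)))
  sf <- subject_band_factors(config, subject)
  set.seed(substream_seed(config$seed, subject, stage_idx, 2L))
  for (ch in config$channels) {
    bp_nc <- stage_band_powers(config, config$stages[1L], ch, sf)
    bp_st <- stage_band_powers(config, stage, ch, sf)
    x_nc <- synth_piece(n, config$fs, bp_nc, config$noise)
    x_st <- synth_piece(n, config$fs, bp_st, config$noise) +
      stage_offset(config, stage, ch)
    samples[ch, ] <- (1 - w) * x_nc + w * x_st + off
  }
  seg <- eeg_segment(samples, config$fs, subject_label(subject), stage,
                     paste0("C", cond))
  attr(seg, "true_onset_s") <- onset
  seg
}

#' Generate skin temperatures and thermal sensation scores
#'
#' Eight-site skin temperatures drift downward with stage severity (so the
#' expected weighted average skin temperature is ordered
#' NC >= CE >= WE >= HB) and 7-point sensation scores come from a rounded,
#' clamped latent Gaussian. Condition modulates drift rates through a
#' severity factor computed from ambient temperature and wind speed. With
#' `physio_noise_sd = 0` the trajectories equal the deterministic drift.
#'
#' @param config a [generator_config()].
#' @return list with data.frames `skin_temperature` (one row per
#'   subject/stage; columns `t_head` ... `t_calf` in deg C) and `sensation`
#'   (integer `score` in `[-3, 3]`).
#' @export
generate_physiology <- function(config) {
  validate_generator_config(config)
  sites <- c("head", "chest", "shoulder", "upperarm",
             "forearm", "hand", "thigh", "calf")
  base <- c(head = 34.2, chest = 34.5, shoulder = 34.0, upperarm = 33.6,
            forearm = 33.2, hand = 32.8, thigh = 33.6, calf = 32.4)
  site_scale <- c(head = 0.6, chest = 0.7, shoulder = 0.7, upperarm = 1.0,
                  forearm = 1.3, hand = 1.8, thigh = 0.9, calf = 1.2)
  stage_drift <- c(NC = 0, CE = -0.4, WE = -1.0, HB = -2.4, PR = -1.2)
  sens_mean <- c(NC = 0.5, CE = -1.2, WE = -1.9, HB = -2.4, PR = -0.6)
  cond_of <- subject_conditions(config)
  sev <- pmax(0.15, 0.7 * (-config$conditions$ambient_c / 20) +
                    0.3 * (config$conditions$wind_ms / 12))
  skin <- list(); sens <- list(); k <- 0L
  for (i in seq_len(config$n_subjects)) {
    set.seed(substream_seed(config$seed, i, 0L, 3L))
    s <- sev[cond_of[i]]
    for (j in seq_along(config$stages)) {
      st <- config$stages[j]
      drift <- if (st %in% names(stage_drift)) stage_drift[[st]] else 0
      temps <- base + drift * s * site_scale +
        stats::rnorm(length(sites), 0, config$physio_noise_sd)
      mu <- (if (st %in% names(sens_mean)) sens_mean[[st]] else 0) * (0.5 + 0.5 * s)
      score <- round(mu + stats::rnorm(1, 0, 0.7 * ifelse(config$physio_noise_sd > 0, 1, 0)))
      score <- max(-3L, min(3L, as.integer(score)))
      k <- k + 1L
      skin[[k]] <- data.frame(subject = subject_label(i), stage = st,
                              condition = paste0("C", cond_of[i]),
                              timestamp = (j - 1) * 300,
                              t(stats::setNames(temps, paste0("t_", sites))))
      sens[[k]] <- data.frame(subject = subject_label(i), stage = st,
                              condition = paste0("C", cond_of[i]),
                              timestamp = (j - 1) * 300, score = score)
    }
  }
  list(skin_temperature = do.call(rbind, skin),
       sensation = do.call(rbind, sens))
}
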