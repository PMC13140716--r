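# Shared fixtures for the suite: small, fast generator configurations.
# Sampling rates are reduced relative to the acquisition hardware; every
# quantity tested (counts, ratios, recovery rates) is invariant to fs.

TABLE_ALPHA_SET <- c("F8", "FC5", "FC2", "FC6", "Cz", "C4", "CP2",
                     "CP5", "CP6", "T7", "T8", "P4", "POz", "P7")

CONSENSUS5 <- c("C4", "T8", "CP6", "F8", "CP2")

one_condition <- function(n) {
  data.frame(ambient_c = 0, wind_ms = 7, n_subjects = n)
}

## minimal single-subject config for signal-level tests (no injected
## effects unless a test passes its own effect_spec)
quick_cfg <- function(seed = 1L, fs = 128, duration_s = 4, n_subjects = 1L,
                      channels = c("Cz", "C4", "T8"),
                      effect_spec = list(), ...) {
  generator_config(n_subjects = n_subjects,
                   conditions = one_condition(n_subjects),
                   fs = fs, duration_s = duration_s, channels = channels,
                   effect_spec = effect_spec, seed = seed, ...)
}

## one synthetic segment for fixture use
quick_segment <- function(seed = 1L, ...) {
  generate_cohort(quick_cfg(seed = seed, ...))$segments[[1L]]
}

## synthetic classifier rows: `n_sub` subjects x 5 stages x `n_win` windows,
## channel features drawn N(mu[stage, channel], 1)
make_rows <- function(mu, n_sub = 6L, n_win = 20L, seed = 1L,
                      channels = colnames(mu)) {
  set.seed(seed)
  out <- list()
  for (s in seq_len(n_sub)) for (st in rownames(mu)) {
    m <- matrix(rnorm(n_win * ncol(mu)), n_win) +
      rep(mu[st, ], each = n_win)
    df <- as.data.frame(m)
    names(df) <- channels
    df$subject <- sprintf("S%02d", s)
    df$stage <- st
    df$window <- seq_len(n_win)
    out[[length(out) + 1L]] <- df
  }
  do.call(rbind, out)
}

stage_mu <- function(channels, effect_channels, effect_stage, delta = 3) {
  mu <- matrix(0, 5, length(channels),
               dimnames = list(c("NC", "CE", "WE", "HB", "PR"), channels))
  mu[effect_stage, effect_channels] <- delta
  mu
}

sinusoid_segment <- function(freq, fs = 1024, duration_s = 2, amp = 1,
                             channel = "Cz") {
  t <- (seq_len(round(fs * duration_s)) - 1) / fs
  eeg_segment(matrix(amp * sin(2 * pi * freq * t), 1,
                     dimnames = list(channel, NULL)), fs = fs,
              subject = "S01", stage = "NC", condition = "C1")
}
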