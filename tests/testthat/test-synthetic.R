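test_that("cohort bookkeeping: one segment per subject and stage, reproducible", {
  cfg <- generator_config(fs = 64, duration_s = 4, seed = 11)
  co <- generate_cohort(cfg)
  expect_length(co$segments, 100L)                    # 20 subjects x 5 stages
  seg <- co$segments[[1L]]
  expect_equal(dim(seg$samples), c(30L, 4L * 64L))
  expect_setequal(unique(vapply(co$segments, function(s) s$stage, "")),
                  c("NC", "CE", "WE", "HB", "PR"))
  # condition allocation follows the 3/3/3/3/3/2/3 design
  subj_cond <- unique(data.frame(
    s = vapply(co$segments, function(s) s$subject, ""),
    c = vapply(co$segments, function(s) s$condition, "")))
  expect_equal(as.integer(table(subj_cond$c)[paste0("C", 1:7)]),
               c(3L, 3L, 3L, 3L, 3L, 2L, 3L))
  # bit-identical under the same seed
  co2 <- generate_cohort(cfg)
  expect_identical(co$segments[[37L]]$samples, co2$segments[[37L]]$samples)
  expect_identical(co$ground_truth, co2$ground_truth)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(n_subjects = 10,
                                conditions = one_condition(9)),
               "sum to n_subjects")
  expect_error(quick_cfg(effect_spec = list(
    CE = list(channels = "Cz", multiplier = -1))), "multipliers")
  expect_error(quick_cfg(onset_spec = c(CE = 12)), "\\[0, 10\\)")
  expect_error(quick_cfg(fs = 50), "beta band")
  expect_error(generator_config(stages = c("NC", "NC", "CE")), "unique")
})

test_that("injected alpha suppression matches the closed-form band-energy ratio", {
  m <- 0.5
  cfg <- generator_config(
    n_subjects = 100L, conditions = one_condition(100L),
    fs = 64, duration_s = 4, channels = c("C4", "Cz"),
    stages = c("NC", "WE"),
    effect_spec = list(WE = list(channels = "C4", multiplier = m)),
    onset_spec = c(WE = 2), noise = list(subject_sd = 0.05), seed = 42)
  co <- generate_cohort(cfg)
  stages <- vapply(co$segments, function(s) s$stage, "")
  alpha <- vapply(co$segments, function(s)
    band_power(s$samples["C4", ], "alpha", fs = s$fs), 0)
  a_nc <- alpha[stages == "NC"]; a_we <- alpha[stages == "WE"]
  expect_lt(mean(a_we), mean(a_nc))
  # ratio of mean band powers equals the analytic expectation ratio
  exp_ratio <- expected_band_power(cfg, "WE", "C4", "alpha") /
    expected_band_power(cfg, "NC", "C4", "alpha")
  ratio <- mean(a_we) / mean(a_nc)
  se_ratio <- ratio * sqrt(var(a_we) / (length(a_we) * mean(a_we)^2) +
                           var(a_nc) / (length(a_nc) * mean(a_nc)^2))
  expect_lt(abs(ratio - exp_ratio), 3 * se_ratio + 0.01)
  # unaffected channel keeps its baseline alpha level
  alpha_cz <- vapply(co$segments[stages == "WE"], function(s)
    band_power(s$samples["Cz", ], "alpha", fs = s$fs), 0)
  expect_lt(abs(mean(alpha_cz) / mean(a_nc) - 1), 0.05)
})

test_that("generator band powers match their analytic expectations", {
  cfg <- quick_cfg(seed = 7, fs = 128, duration_s = 4, channels = "Cz",
                   n_subjects = 60L, noise = list(subject_sd = 0))
  co <- generate_cohort(cfg)
  nc <- Filter(function(s) s$stage == "NC", co$segments)
  for (b in c("delta", "theta", "alpha", "beta")) {
    meas <- vapply(nc, function(s) band_power(s$samples["Cz", ], b, fs = s$fs), 0)
    expe <- expected_band_power(cfg, "NC", "Cz", b)
    # 3 MC standard errors plus a 3% allowance for spectral leakage of the
    # phase-diffusing oscillation across band edges
    tol <- 3 * sd(meas) / sqrt(length(meas)) + 0.03 * expe
    expect_lt(abs(mean(meas) - expe), tol)
  }
})

test_that("onset segments switch spectral statistics at the true onset", {
  m <- sqrt(0.3)
  cfg <- quick_cfg(seed = 3, fs = 128, duration_s = 10, channels = "C4",
                   effect_spec = list(WE = list(channels = "C4", multiplier = m)),
                   onset_spec = c(WE = 2.0), noise = list(subject_sd = 0))
  ratios <- vapply(1:60, function(r) {
    cfg$seed <- 3L + r
    seg <- generate_onset_segment(cfg, 1, "WE")
    nc <- generate_cohort(cfg)$segments[[1L]]
    blocks <- vapply(0:9, function(b)
      band_power(seg$samples["C4", (b * 128 + 1):((b + 1) * 128)],
                 "alpha", fs = 128), 0)
    nc_blocks <- vapply(0:9, function(b)
      band_power(nc$samples["C4", (b * 128 + 1):((b + 1) * 128)],
                 "alpha", fs = 128), 0)
    c(pre = mean(blocks[1:2]), post = mean(blocks[4:10]),
      nc = mean(nc_blocks))
  }, numeric(3))
  # pre-onset blocks carry baseline statistics (same level as pure NC draws)
  expect_lt(abs(mean(ratios["pre", ]) / mean(ratios["nc", ]) - 1), 0.15)
  # post-onset blocks carry the suppressed stage level
  exp_post <- expected_band_power(cfg, "WE", "C4", "alpha")
  expect_lt(abs(mean(ratios["post", ]) / exp_post - 1), 0.10)
  # block-wise power drops at the onset block
  expect_lt(mean(ratios["post", ]) / mean(ratios["pre", ]), 0.5)
})

test_that("onset boundary cases behave as specified", {
  cfg <- quick_cfg(seed = 5, fs = 128, duration_s = 6, channels = "C4",
                   effect_spec = list(CE = list(channels = "C4", multiplier = 0.4)),
                   onset_spec = c(CE = 0.5), noise = list(subject_sd = 0))
  # onset 0: the whole segment carries stage statistics
  seg0 <- generate_onset_segment(cfg, 1, "CE", onset_s = 0)
  a0 <- band_power(seg0$samples["C4", ], "alpha", fs = 128)
  expect_lt(a0, expected_band_power(cfg, "NC", "C4", "alpha") * 0.5)
  # onset at/after the segment end is an error
  expect_error(generate_onset_segment(cfg, 1, "CE", onset_s = 6), "precede")
  # a stage without configured onset is an error
  expect_error(generate_onset_segment(cfg, 1, "HB"), "onset")
  # multiplier 1: expected band powers indistinguishable from baseline
  cfg1 <- quick_cfg(seed = 6, fs = 128, duration_s = 6, channels = "C4",
                    effect_spec = list(CE = list(channels = "C4", multiplier = 1)),
                    onset_spec = c(CE = 2), noise = list(subject_sd = 0))
  expect_equal(expected_band_power(cfg1, "CE", "C4", "alpha"),
               expected_band_power(cfg1, "NC", "C4", "alpha"))
})

test_that("physiology: sensation bounds, WAST ordering and noise-off identity", {
  cfg <- generator_config(fs = 64, duration_s = 1, seed = 19)
  ph <- generate_physiology(cfg)
  expect_true(all(ph$sensation$score >= -3 & ph$sensation$score <= 3))
  w <- wast(ph$skin_temperature)
  stage <- ph$skin_temperature$stage
  # expected ordering of stage means, separated well beyond 5 standard errors
  means <- tapply(w, stage, mean)
  expect_true(means[["NC"]] >= means[["CE"]])
  expect_true(means[["CE"]] >= means[["WE"]])
  expect_true(means[["WE"]] >= means[["HB"]])
  se_hb <- sd(w[stage == "HB"]) / sqrt(sum(stage == "HB"))
  expect_gt(means[["NC"]] - means[["HB"]], 5 * se_hb)
  # zero noise: trajectories equal the deterministic drift exactly
  cfg0 <- generator_config(fs = 64, duration_s = 1, seed = 19,
                           physio_noise_sd = 0)
  ph0a <- generate_physiology(cfg0)
  ph0b <- generate_physiology(cfg0)
  expect_identical(ph0a, ph0b)
  expect_equal(sd(wast(ph0a$skin_temperature)[ph0a$skin_temperature$stage == "NC"]), 0)
})
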