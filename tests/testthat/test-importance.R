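test_that("window segmentation geometry follows the rounding contract", {
  seg <- quick_segment(seed = 2, fs = 1024, duration_s = 5, channels = c("Cz", "C4"))
  rows <- window_features(seg)
  expect_equal(nrow(rows), 100L)
  starts <- rows$start_s * 1024
  expect_equal(starts, round((0:99) * (5120 - 512) / 99))
  expect_true(all(diff(starts) %in% c(46, 47)))
  # count = 2: endpoints only
  two <- window_features(seg, count = 2L)
  expect_equal(two$start_s * 1024, c(0, 5120 - 512))
  # the feature is the signed mean of the window
  expect_equal(two$Cz[1L], mean(seg$samples["Cz", 1:512]))
  expect_error(window_features(seg, span_ms = 400, width_ms = 500), "width")
  expect_error(window_features(seg, span_ms = 6000), "span")
})

test_that("classifiers separate separable stages and stay at chance on shuffled labels", {
  channels <- paste0("ch", 1:6)
  mu <- matrix(seq(0, 12, length.out = 5) %o% rep(1, 6), 5,
               dimnames = list(c("NC", "CE", "WE", "HB", "PR"), channels))
  rows <- make_rows(mu, n_sub = 6, n_win = 20, seed = 3, channels = channels)
  fit <- fit_stage_classifiers(rows, task = "multiclass", model_kind = "rf",
                               seed = 9, cv_folds = 3)
  expect_gte(fit$accuracy, 0.95)
  expect_true(fit$acceptable)
  # label shuffling destroys the association: accuracy within 3 SE of 1/5
  set.seed(17)
  rows_sh <- rows
  rows_sh$stage <- sample(rows$stage)
  fit_sh <- fit_stage_classifiers(rows_sh, task = "multiclass",
                                  model_kind = "rf", seed = 9, cv_folds = 3)
  se <- sqrt(0.2 * 0.8 / nrow(rows))
  expect_lt(abs(fit_sh$accuracy - 0.2), 3 * se + 0.02)
  expect_false(fit_sh$acceptable)
})

test_that("fits are deterministic and grouped folds demand all classes", {
  channels <- paste0("ch", 1:4)
  rows <- make_rows(stage_mu(channels, "ch1", "CE"), n_sub = 4, n_win = 10,
                    seed = 5, channels = channels)
  f1 <- fit_stage_classifiers(rows, task = "ovr", stage = "CE",
                              model_kind = "rf", seed = 21, cv_folds = 2)
  f2 <- fit_stage_classifiers(rows, task = "ovr", stage = "CE",
                              model_kind = "rf", seed = 21, cv_folds = 2)
  expect_identical(f1$accuracy, f2$accuracy)
  expect_identical(f1$fold_accuracies, f2$fold_accuracies)
  # one subject holds every CE row -> its fold's training part lacks a class
  rows_single <- rows[!(rows$stage == "CE") | rows$subject == "S01", ]
  expect_error(fit_stage_classifiers(rows_single, task = "ovr", stage = "CE",
                                     model_kind = "rf", seed = 21,
                                     cv_folds = 2),
               "class absent")
  # mlp and svm kinds run through the same interface
  for (kind in c("mlp", "svm")) {
    fk <- fit_stage_classifiers(rows, task = "ovr", stage = "CE",
                                model_kind = kind, seed = 3, cv_folds = 2)
    expect_true(is.finite(fk$accuracy))
  }
})

test_that("sampled Shapley values obey efficiency, nullity and symmetry", {
  channels <- c("A", "B", "Adup", "Z")
  mu <- stage_mu(channels, c("A", "Adup"), "CE", delta = 3)
  mu["CE", "B"] <- 1.5
  rows <- make_rows(mu, n_sub = 6, n_win = 15, seed = 11, channels = channels)
  rows$Adup <- rows$A     # exact duplicate: the RBF kernel treats the pair
                          # symmetrically, so the fitted score is exactly
                          # exchangeable in (A, Adup)
  rows$Z <- 0             # constant feature: structurally ignored
  # (e1071 warns that the constant column cannot be scaled - intentional here)
  fit <- suppressWarnings(
    fit_stage_classifiers(rows, task = "ovr", stage = "CE",
                          model_kind = "svm", seed = 13, cv_folds = 2))
  imp <- shapley_importance(fit, rows[rows$stage == "CE", ],
                            n_samples = 256, seed = 7, max_rows = 25)
  # efficiency holds exactly per explained row
  expect_equal(rowSums(imp$phi),
               imp$row_scores - imp$background_score, tolerance = 1e-10)
  # a feature the model ignores scores (essentially) zero
  expect_lte(imp$scores[["Z"]], 0.02 * max(imp$scores))
  # duplicated, equally informative features get equal credit
  expect_lt(abs(imp$scores[["A"]] - imp$scores[["Adup"]]) /
              max(imp$scores[["A"]], imp$scores[["Adup"]]), 0.10)
  expect_error(shapley_importance(fit, rows, n_samples = 0), "n_samples")
})

test_that("sampled Shapley matches exact subset enumeration on few features", {
  channels <- paste0("ch", 1:5)
  mu <- stage_mu(channels, c("ch1", "ch2"), "CE", delta = c(2.5))
  rows <- make_rows(mu, n_sub = 4, n_win = 12, seed = 23, channels = channels)
  fit <- fit_stage_classifiers(rows, task = "ovr", stage = "CE",
                               model_kind = "rf", seed = 29, cv_folds = 2)
  explain <- rows[rows$stage == "CE", ]
  set.seed(31)
  pick <- sample(nrow(explain), 6)
  explain <- explain[pick, ]
  X <- as.matrix(explain[, channels])
  bg <- colMeans(as.matrix(explain[, channels]))  # estimator background:
                                                  # means of the explained rows
  score_fun <- function(m) {
    colnames(m) <- channels
    thermoeeg:::predict_score(fit, m)
  }
  imp <- shapley_importance(fit, explain, n_samples = 1024, seed = 37,
                            max_rows = 6)
  rng <- diff(range(imp$row_scores, imp$background_score))
  for (i in seq_along(pick)) {
    exact <- oracle_shapley_exact(score_fun, X[i, ], bg)
    expect_lt(max(abs(imp$phi[i, ] - exact)), 0.05 * max(rng, 1e-6))
  }
})

test_that("channels carrying injected stage effects dominate the importance ranking", {
  effect_channels <- c("C4", "T8")
  n_rep <- 12L
  top5_hits <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(
      n_subjects = 5, conditions = one_condition(5), fs = 128,
      duration_s = 6, channels = c("C4", "T8", "Cz", "Fp1", "Oz", "P7", "F8", "CP2"),
      effect_spec = list(CE = list(channels = effect_channels,
                                   multiplier = 0.74, offset_uv = 4)),
      seed = 5000 + r)
    co <- generate_cohort(cfg)
    rows <- cohort_window_features(co$segments, count = 30L)
    fit <- fit_stage_classifiers(rows, task = "ovr", stage = "CE",
                                 model_kind = "rf", seed = 100 + r,
                                 cv_folds = 3)
    imp <- shapley_importance(fit, rows[rows$stage == "CE", ],
                              n_samples = 32, seed = 200 + r, max_rows = 20)
    if (all(effect_channels %in% utils::head(imp$ranking, 5L)))
      top5_hits <- top5_hits + 1L
  }
  expect_gte(top5_hits / n_rep, 0.80)
})

test_that("consensus set algebra: intersections, disjoint sets and montage checks", {
  stat_set <- c("C4", "T8", "Cz")
  cs <- consensus(stat_set, c("T8", "F7", "C4", "P3", "O1"), k = 5)
  expect_setequal(cs$intersection, c("T8", "C4"))
  expect_true(all(cs$intersection %in% cs$statistical))
  expect_true(all(cs$intersection %in% cs$importance))
  # disjoint top-k within one montage: legitimately empty
  cs2 <- consensus(stat_set, c("F7", "P3", "O1", "Fp1", "Fz", "C4"), k = 5)
  expect_length(cs2$intersection, 0L)
  # top-k restriction honoured
  cs3 <- consensus(stat_set, c("F7", "P3", "C4"), k = 2)
  expect_length(cs3$intersection, 0L)
  # disjoint channel universes indicate different montages
  expect_error(consensus(c("LEFT1", "LEFT2"), c("C4", "Cz", "T8")),
               "disjoint")
})
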