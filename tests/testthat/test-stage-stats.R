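test_that("Welch ANOVA matches the textbook formula oracle", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  got <- welch_anova(groups)
  exp <- oracle_welch(groups)
  expect_equal(got$F, exp$F, tolerance = 1e-9)
  expect_equal(got$df2, exp$df2, tolerance = 1e-9)
  expect_equal(got$p, exp$p, tolerance = 1e-9)
  # random heteroscedastic fixtures
  set.seed(8)
  for (i in 1:10) {
    g <- lapply(1:4, function(j) rnorm(3 + j, mean = j, sd = j))
    expect_equal(welch_anova(g)$F, oracle_welch(g)$F, tolerance = 1e-9)
    expect_equal(welch_anova(g)$p, oracle_welch(g)$p, tolerance = 1e-9)
  }
})

test_that("Welch ANOVA: equal means, scaling and degeneracy", {
  same <- list(c(1, 2, 3), c(1, 2, 3))
  got <- welch_anova(same)
  expect_equal(got$F, 0)
  expect_equal(got$p, 1)
  g <- list(c(1, 2, 3), c(2, 4, 5), c(1, 1.5, 4))
  expect_equal(welch_anova(g)$F, welch_anova(lapply(g, `*`, 10))$F,
               tolerance = 1e-9)
  expect_error(welch_anova(list(c(1, 2, 3))), "2 groups")
  expect_error(welch_anova(list(c(1, 2), c(3, 3))), "zero variance")
  # relation to the classical equal-variance F: with equal group variances
  # the Welch numerator equals the classical F exactly (the 1 + B correction
  # is the only difference), and the correction vanishes as groups grow
  set.seed(2)
  gb <- lapply(1:3, function(j) rnorm(10, mean = j))
  gb <- lapply(gb, function(v) (v - mean(v)) / sd(v) + mean(v))  # equal variances
  classical <- oneway.test(unlist(gb) ~ factor(rep(1:3, each = 10)),
                           var.equal = TRUE)
  k <- 3; n <- 10
  B <- 2 * (k - 2) / (k^2 - 1) * sum(rep((1 - 1 / k)^2 / (n - 1), k))
  expect_equal(welch_anova(gb)$F * (1 + B), unname(classical$statistic),
               tolerance = 1e-9)
  gbig <- lapply(gb, function(v) {
    vv <- rep(v, 200) + rnorm(2000, 0, 1e-8)    # same means/variances, n=2000
    (vv - mean(vv)) / sd(vv) * sd(v) + mean(v)
  })
  classical_big <- oneway.test(
    unlist(gbig) ~ factor(rep(1:3, each = 2000)), var.equal = TRUE)
  expect_equal(welch_anova(gbig)$F, unname(classical_big$statistic),
               tolerance = 1e-3)
})

test_that("repeated-measures ANOVA matches aov and the sum-of-squares oracle", {
  mat <- matrix(c(3, 5, 7,
                  4, 6, 9,
                  2, 4, 6,
                  5, 8, 9), nrow = 4, byrow = TRUE)
  got <- rm_anova(mat)
  expect_equal(got$df1, 2L)
  expect_equal(got$df2, 6L)
  orc <- oracle_rm(mat)
  expect_equal(got$F, orc$F, tolerance = 1e-9)
  expect_equal(got$partial_eta2, orc$partial_eta2, tolerance = 1e-9)
  # independent route: aov with a subject error stratum
  df <- data.frame(y = as.vector(mat),
                   subject = factor(rep(1:4, 3)),
                   stage = factor(rep(1:3, each = 4)))
  a <- summary(aov(y ~ stage + Error(subject), data = df))[[2L]][[1L]]
  expect_equal(got$F, a[["F value"]][1L], tolerance = 1e-9)
  expect_equal(got$p, a[["Pr(>F)"]][1L], tolerance = 1e-9)
})

test_that("repeated-measures ANOVA shape, null and error behaviour", {
  set.seed(4)
  m20 <- matrix(rnorm(100), 20, 5)
  got <- rm_anova(m20)
  expect_equal(c(got$df1, got$df2), c(4L, 76L))
  expect_gte(got$partial_eta2, 0)
  expect_lte(got$partial_eta2, 1)
  # all stages identical per subject: no stage effect
  flat <- matrix(rep(rnorm(6), 4), nrow = 6)
  expect_equal(rm_anova(flat)$F, 0)
  expect_equal(rm_anova(flat)$partial_eta2, 0)
  bad <- m20; bad[3, 2] <- NA
  expect_error(rm_anova(bad), "missing")
})

test_that("BH adjustment equals brute-force step-up on random vectors", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  set.seed(11)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
    expect_true(all(bh_fdr(p) >= p))
    # invariance to input ordering (up to index bookkeeping)
    o <- sample(length(p))
    expect_equal(bh_fdr(p)[o], bh_fdr(p[o]), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("effect-size conversion reproduces the closed form", {
  expect_equal(round(eta2_to_f(0.074), 2), 0.28)
  expect_equal(round(eta2_to_f(0.174), 2), 0.46)
  expect_equal(eta2_to_f(0), 0)
  expect_equal(eta2_to_f(0.5), 1)
  expect_error(eta2_to_f(1), "\\[0, 1\\)")
})

test_that("sample-size search is consistent with the quadrature power oracle", {
  n_star <- rm_sample_size(f = 0.25, alpha = 0.05, power = 0.80, m = 5,
                           rho = 0.5, epsilon = 1)
  expect_gte(oracle_rm_power(n_star, 0.25, 0.05, 5, 0.5), 0.80)
  expect_lt(oracle_rm_power(n_star - 1, 0.25, 0.05, 5, 0.5), 0.80)
  # power curve nondecreasing in N
  pw <- vapply(5:40, rm_power, 0, f = 0.25, alpha = 0.05, m = 5, rho = 0.5)
  expect_true(all(diff(pw) > 0))
  # doubling f can only shrink the requirement
  expect_lte(rm_sample_size(f = 0.5, m = 5), n_star)
  # pf(ncp) route and quadrature agree
  expect_equal(rm_power(20, 0.25, 0.05, 5, 0.5),
               oracle_rm_power(20, 0.25, 0.05, 5, 0.5), tolerance = 1e-6)
})

test_that("pooling check holds its nominal level and detects condition effects", {
  n_rep <- 60L
  poolable <- logical(n_rep)
  poolable_perm <- logical(n_rep)
  raw_reject <- 0L; n_raw <- 0L
  for (r in seq_len(n_rep)) {
    cfg <- generator_config(fs = 64, duration_s = 2, seed = 3000 + r,
                            channels = c("Cz", "C4", "Fp1"),
                            effect_spec = list())
    ft <- compute_feature_table(generate_cohort(cfg)$segments)
    pc <- pooling_check(ft)
    poolable[r] <- pc$poolable
    raw_reject <- raw_reject + sum(pc$per_stage$welch_p < 0.05)
    n_raw <- n_raw + nrow(pc$per_stage)
    # label exchangeability: permuting conditions must look the same
    ft_perm <- ft
    map <- sample(unique(ft$condition))
    names(map) <- unique(ft$condition)
    ft_perm$condition <- unname(map[ft$condition])
    poolable_perm[r] <- pooling_check(ft_perm)$poolable
  }
  expect_gte(mean(poolable), 0.90)
  expect_gte(mean(poolable_perm), 0.90)
  # per-stage raw Welch rejections stay near the nominal level
  expect_lte(raw_reject, qbinom(0.999, n_raw, 0.05))
  # an injected large condition effect flips the flag
  cfg_eff <- generator_config(fs = 64, duration_s = 2, seed = 77,
                              channels = c("Cz", "C4", "Fp1"),
                              effect_spec = list(),
                              condition_offsets_uv = c(0, 0, 0, 0, 6, 6, 6))
  ft_eff <- compute_feature_table(generate_cohort(cfg_eff)$segments)
  expect_false(pooling_check(ft_eff)$poolable)
  expect_error(pooling_check(ft_eff[ft_eff$condition == "C1", ]), "2 conditions")
})

test_that("channel battery output invariants on a small cohort", {
  cfg <- generator_config(
    n_subjects = 8, conditions = one_condition(8), fs = 64, duration_s = 4,
    channels = c("C4", "T8", "Fp1", "Oz"),
    effect_spec = list(CE = list(channels = c("C4", "T8"), multiplier = 0.6),
                       WE = list(channels = c("C4", "T8"), multiplier = 0.5),
                       HB = list(channels = c("C4", "T8"), multiplier = 0.7),
                       PR = list(channels = c("C4", "T8"), multiplier = 0.7)),
    seed = 31)
  ft <- compute_feature_table(generate_cohort(cfg)$segments)
  bat <- channel_battery(ft, "pr_alpha")
  expect_setequal(bat$channel, c("C4", "T8", "Fp1", "Oz"))
  expect_true(all(bat$p_fdr >= bat$p_raw))
  expect_true(all(bat$partial_eta2 >= 0 & bat$partial_eta2 <= 1))
  expect_true(all(bat$test_used %in% c("rm", "welch")))
  expect_setequal(significant_channels(bat), c("C4", "T8"))
  # incomplete channels are reported, not dropped
  ft_bad <- ft[!(ft$channel == "Oz" & ft$subject == "S01" & ft$stage == "CE"), ]
  expect_error(channel_battery(ft_bad, "pr_alpha"), "Oz")
})
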