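#' Stage-wise statistical battery
#'
#' Assumption checks (Shapiro-Wilk, Levene, Mauchly), Welch's heteroscedastic
#' ANOVA, one-way repeated-measures ANOVA with partial eta squared,
#' Benjamini-Hochberg FDR correction, the eta-squared/Cohen's f conversion,
#' and the a priori sample-size computation for a repeated-measures design.
#'
#' @name stage_stats
NULL

#' Welch's heteroscedastic one-way ANOVA
#'
#' @param groups list of numeric vectors, one per group; each group needs at
#'   least two observations and nonzero variance.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  if (any(vapply(groups, stats::var, 0) <= 0))
    stop("degenerate group with zero variance")
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), sizes))
  ht <- stats::oneway.test(values ~ g, var.equal = FALSE)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1L]),
       df2 = unname(ht$parameter[2L]), p = unname(ht$p.value))
}

#' One-way repeated-measures ANOVA
#'
#' Classical subject x stage decomposition: `df1 = m - 1`,
#' `df2 = (n - 1)(m - 1)`, `F = MS_stage / MS_error` and partial eta squared
#' `SS_stage / (SS_stage + SS_error)`. Missing cells are an error; no
#' imputation is attempted.
#'
#' @param mat numeric matrix, subjects in rows, stages in columns.
#' @return list with `F`, `df1`, `df2`, `p`, `partial_eta2`, and the
#'   underlying sums of squares.
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("missing or non-finite cells in subjects x stages matrix")
  n <- nrow(mat); m <- ncol(mat)
  if (n < 2L || m < 2L) stop("need at least 2 subjects and 2 stages")
  grand <- mean(mat)
  ss_stage <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- m * sum((rowMeans(mat) - grand)^2)
  ss_total <- sum((mat - grand)^2)
  ss_error <- ss_total - ss_stage - ss_subj
  df1 <- m - 1L; df2 <- (n - 1L) * (m - 1L)
  if (ss_error <= 0) {
    F <- if (ss_stage > 0) Inf else 0
  } else {
    F <- (ss_stage / df1) / (ss_error / df2)
  }
  p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  list(F = F, df1 = df1, df2 = df2, p = p,
       partial_eta2 = if (ss_stage + ss_error > 0) ss_stage / (ss_stage + ss_error) else 0,
       ss_stage = ss_stage, ss_error = ss_error, ss_subject = ss_subj)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, monotone, capped at 1 and returned in the
#' input order.
#'
#' @param p_values numeric vector of raw p values in `[0, 1]`.
#' @return adjusted p values.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Convert partial eta squared to Cohen's f
#'
#' `f = sqrt(eta2 / (1 - eta2))`.
#'
#' @param partial_eta2 value in `[0, 1)`.
#' @return Cohen's f.
#' @export
eta2_to_f <- function(partial_eta2) {
  if (any(partial_eta2 < 0 | partial_eta2 >= 1))
    stop("partial eta squared must lie in [0, 1)")
  sqrt(partial_eta2 / (1 - partial_eta2))
}

#' Power of the repeated-measures stage test
#'
#' Noncentral-F power under the within-factors convention of the standard
#' power-analysis tools: `df1 = (m - 1) eps`, `df2 = (N - 1)(m - 1) eps`,
#' noncentrality `lambda = f^2 N m eps / (1 - rho)`.
#'
#' @param n number of subjects.
#' @param f Cohen's f effect size.
#' @param alpha significance level.
#' @param m number of repeated measures.
#' @param rho assumed correlation among repeated measures.
#' @param epsilon nonsphericity correction in `(1/(m-1), 1]`.
#' @return achieved power.
#' @export
rm_power <- function(n, f, alpha = 0.05, m, rho = 0.5, epsilon = 1) {
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  lambda <- f^2 * n * m * epsilon / (1 - rho)
  stats::pf(stats::qf(1 - alpha, df1, df2), df1, df2, ncp = lambda,
            lower.tail = FALSE)
}

#' Minimum sample size for the repeated-measures design
#'
#' Smallest number of subjects whose noncentral-F power under [rm_power()]
#' reaches the target.
#'
#' @inheritParams rm_power
#' @param power target power in `(0, 1)`.
#' @param n_max give up beyond this many subjects.
#' @return minimum number of subjects.
#' @export
rm_sample_size <- function(f, alpha = 0.05, power = 0.80, m, rho = 0.5,
                           epsilon = 1, n_max = 1e6) {
  stopifnot(f > 0, alpha > 0, alpha < 1, power > 0, power < 1, m >= 2,
            rho >= 0, rho < 1, epsilon > 1 / (m - 1), epsilon <= 1)
  n <- 2L
  while (n <= n_max) {
    if (rm_power(n, f, alpha, m, rho, epsilon) >= power) return(n)
    n <- n + 1L
  }
  stop("target power unreachable within n_max subjects")
}

## Mauchly's sphericity test on a subjects x stages matrix; needs more
## subjects than stages for a full-rank within-subject covariance
mauchly_p <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) <= ncol(mat)) return(NA_real_)
  fit <- stats::lm(mat ~ 1)
  out <- try(suppressWarnings(stats::mauchly.test(fit, X = ~1)),
             silent = TRUE)
  if (inherits(out, "try-error")) return(NA_real_)
  unname(out$p.value)
}

## Levene's test (deviation-from-mean form) across groups; undefined when
## every group has <= 2 observations (within-pair absolute deviations are
## identical, so the auxiliary ANOVA is a perfect fit)
levene_p <- function(values, groups) {
  g <- factor(groups)
  if (max(table(g)) <= 2L) return(NA_real_)
  df <- data.frame(v = values, g = g)
  out <- suppressWarnings(car::leveneTest(v ~ g, data = df, center = mean))
  out[["Pr(>F)"]][1L]
}

## Shapiro-Wilk on within-group centred residuals
shapiro_resid_p <- function(values, groups) {
  res <- unlist(lapply(split(values, groups), function(v) v - mean(v)))
  if (length(res) < 3L || stats::sd(res) == 0) return(NA_real_)
  stats::shapiro.test(res)$p.value
}

#' Condition-pooling check
#'
#' For each stage, tests whether per-subject mean amplitudes differ across
#' environmental conditions: Shapiro-Wilk on the centred residuals, Levene's
#' variance-homogeneity test, and both the classical and Welch's
#' heteroscedastic ANOVA across conditions. The poolability decision gates
#' on the classical F test (exact under the normality the Shapiro check
#' verifies; Welch's test over-rejects badly with only 2-3 subjects per
#' condition), after Benjamini-Hochberg correction of the per-stage p
#' values across the stage family. Welch's results are always reported
#' alongside.
#'
#' @param features a [compute_feature_table()] data.frame (or any data.frame
#'   with `subject`, `stage`, `condition` and a feature column).
#' @param feature column to test (default `mean_amp`).
#' @param alpha significance level for the poolability decision.
#' @return list with `per_stage` (data.frame of shapiro/levene/anova/welch
#'   results), `poolable` flag and `alpha`.
#' @export
pooling_check <- function(features, feature = "mean_amp", alpha = 0.05) {
  if (length(unique(features$condition)) < 2L)
    stop("pooling check needs at least 2 conditions")
  agg <- stats::aggregate(features[[feature]],
                          by = list(subject = features$subject,
                                    stage = features$stage,
                                    condition = features$condition),
                          FUN = mean)
  names(agg)[4L] <- "value"
  stages <- unique(agg$stage)
  rows <- lapply(stages, function(st) {
    d <- agg[agg$stage == st, ]
    groups <- split(d$value, d$condition)
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L) stop("stage ", st, " has a single condition")
    w <- welch_anova(groups)
    cl <- stats::oneway.test(value ~ factor(condition), data = d,
                             var.equal = TRUE)
    data.frame(stage = st,
               shapiro_p = shapiro_resid_p(d$value, d$condition),
               levene_p = levene_p(d$value, d$condition),
               anova_F = unname(cl$statistic), anova_p = unname(cl$p.value),
               welch_F = w$F, welch_df1 = w$df1, welch_df2 = w$df2,
               welch_p = w$p)
  })
  per_stage <- do.call(rbind, rows)
  per_stage$anova_p_fdr <- bh_fdr(per_stage$anova_p)
  per_stage$welch_p_fdr <- bh_fdr(per_stage$welch_p)
  list(per_stage = per_stage,
       poolable = all(per_stage$anova_p_fdr > alpha),
       alpha = alpha)
}

#' Per-channel stage battery
#'
#' Aggregates a windowed feature to one value per subject x stage x channel,
#' then tests each channel for a stage effect: repeated-measures ANOVA by
#' default, falling back to Welch's ANOVA when Mauchly's sphericity check or
#' Levene's variance check fails at `assumption_alpha`. Both results are
#' always reported. Benjamini-Hochberg correction is applied across the
#' channel family, and significance is called at FDR-corrected
#' `p < alpha`.
#'
#' @param features a [compute_feature_table()] data.frame.
#' @param feature feature column, e.g. `"pr_alpha"`.
#' @param alpha FDR-corrected significance threshold.
#' @param assumption_alpha level of the assumption gates.
#' @return a `stage_stats` data.frame: one row per channel with F, df,
#'   raw/FDR p, partial eta squared, the assumption p values, the test used
#'   and the significance flag.
#' @export
channel_battery <- function(features, feature = "pr_alpha", alpha = 0.05,
                            assumption_alpha = 0.05) {
  agg <- stats::aggregate(features[[feature]],
                          by = list(subject = features$subject,
                                    stage = features$stage,
                                    channel = features$channel),
                          FUN = mean)
  names(agg)[4L] <- "value"
  stages <- unique(features$stage)
  channels <- unique(features$channel)
  rows <- lapply(channels, function(ch) {
    d <- agg[agg$channel == ch, ]
    mat <- tapply(d$value, list(d$subject, d$stage), mean)
    mat <- mat[, stages, drop = FALSE]
    if (any(is.na(mat)))
      stop("incomplete subject x stage data for channel ", ch)
    rm <- rm_anova(mat)
    wl <- welch_anova(split(d$value, d$stage))
    mau <- mauchly_p(mat)
    lev <- levene_p(d$value, d$stage)
    gate_fail <- (!is.na(mau) && mau < assumption_alpha) ||
      (!is.na(lev) && lev < assumption_alpha)
    data.frame(channel = ch,
               F_rm = rm$F, df1_rm = rm$df1, df2_rm = rm$df2, p_rm = rm$p,
               partial_eta2 = rm$partial_eta2,
               F_welch = wl$F, df1_welch = wl$df1, df2_welch = wl$df2,
               p_welch = wl$p,
               mauchly_p = mau, levene_p = lev,
               test_used = if (gate_fail) "welch" else "rm",
               p_raw = if (gate_fail) wl$p else rm$p)
  })
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_fdr(out$p_raw)
  out$significant <- out$p_fdr < alpha
  attr(out, "feature") <- feature
  attr(out, "alpha") <- alpha
  class(out) <- c("stage_stats", "data.frame")
  out
}

#' @export
print.stage_stats <- function(x, ...) {
  cat("<stage_stats> feature:", attr(x, "feature"),
      "- significant channels (FDR <", attr(x, "alpha"), "):\n  ",
      paste(x$channel[x$significant], collapse = ", "), "\n")
  NextMethod()
}

#' Significant channel set of a battery
#'
#' @param battery a [channel_battery()] result.
#' @return character vector of FDR-significant channels.
#' @export
significant_channels <- function(battery) {
  as.character(battery$channel[battery$significant])
}
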