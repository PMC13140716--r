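# Independent oracles used by the test suite. Each is written directly from
# the textbook definition and stays independent of the package's code paths.

## Welch's heteroscedastic one-way ANOVA from the textbook formulas
oracle_welch <- function(groups) {
  k <- length(groups)
  n <- lengths(groups)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, var, 0)
  w <- n / v
  W <- sum(w)
  mbar <- sum(w * m) / W
  A <- sum(w * (m - mbar)^2) / (k - 1)
  B <- 2 * (k - 2) / (k^2 - 1) * sum((1 - w / W)^2 / (n - 1))
  F <- A / (1 + B)
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * sum((1 - w / W)^2 / (n - 1)))
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

## one-way repeated-measures ANOVA by explicit sum-of-squares decomposition
oracle_rm <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  grand <- mean(mat)
  ss_stage <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- m * sum((rowMeans(mat) - grand)^2)
  ss_err <- sum((mat - grand)^2) - ss_stage - ss_subj
  F <- (ss_stage / (m - 1)) / (ss_err / ((n - 1) * (m - 1)))
  list(F = F, partial_eta2 = ss_stage / (ss_stage + ss_err))
}

## brute-force Benjamini-Hochberg step-up evaluation
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

## noncentral-F power by numerical quadrature of the density (independent of
## the pf(ncp) CDF route used by the implementation)
oracle_rm_power <- function(n, f, alpha, m, rho, epsilon = 1) {
  df1 <- (m - 1) * epsilon
  df2 <- (n - 1) * (m - 1) * epsilon
  lambda <- f^2 * n * m * epsilon / (1 - rho)
  crit <- qf(1 - alpha, df1, df2)
  integrate(function(x) df(x, df1, df2, ncp = lambda), crit, Inf,
            rel.tol = 1e-9)$value
}

## exact Shapley values by full subset enumeration against a single
## background point (matches the estimator's marginal-means background)
oracle_shapley_exact <- function(score_fun, x, background) {
  p <- length(x)
  phi <- numeric(p)
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), p))
  vals <- apply(subsets, 1L, function(s) {
    z <- background
    z[as.logical(s)] <- x[as.logical(s)]
    score_fun(matrix(z, nrow = 1L))
  })
  sizes <- rowSums(subsets)
  for (j in seq_len(p)) {
    without <- which(!subsets[[j]])
    for (row in without) {
      s <- sizes[row]
      with_row <- row + 2^(j - 1)          # expand.grid bit order
      weight <- factorial(s) * factorial(p - s - 1) / factorial(p)
      phi[j] <- phi[j] + weight * (vals[with_row] - vals[row])
    }
  }
  phi
}
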