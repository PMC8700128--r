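test_that("VAR least squares recovers known coefficients", {
  set.seed(41)
  # bivariate VAR(1) with known matrix, long sample
  n <- 1e5
  A <- matrix(c(0.5, 0.2, -0.3, 0.4), 2, 2, byrow = TRUE)
  x <- matrix(0, n, 2)
  e <- matrix(rnorm(2 * n), n, 2)
  for (t in 2:n) x[t, ] <- A %*% x[t - 1, ] + e[t, ]
  fit <- fit_var(x, P = 1)
  expect_true(all(abs(fit$A[, , 1] - A) < 0.01))
  # white-noise panel: coefficients within 3 SE of zero in the bulk
  set.seed(42)
  wn <- matrix(rnorm(3000 * 3), ncol = 3)
  fw <- fit_var(wn, P = 1)
  se <- sqrt(mean(fw$sigma2) / nrow(wn))
  expect_lt(mean(abs(fw$A[, , 1]) > 3 * se), 0.2)
  # S2 printed equation: X3 <- 0.4 * X1 lag 3
  p2 <- test_panel("S2", seed = 5)
  f2 <- fit_var(p2, P = 3)
  expect_lt(abs(f2$A[3, 1, 3] - 0.4), 0.05)
  expect_lt(abs(f2$A[3, 3, 2] - (-0.3)), 0.05)
  expect_error(fit_var(wn[1:10, ], P = 3))
})

test_that("CGCI is nonnegative, matches the two-regression oracle, and detects", {
  set.seed(43)
  n <- 1e4
  x <- rnorm(n)
  y <- c(0, 0.8 * x[-n]) + rnorm(n)
  d <- cbind(x = x, y = y)
  got <- cgci(d, "x", "y", P = 1)
  # independent oracle: two explicit lm fits
  dy <- y[2:n]; lx <- x[1:(n - 1)]; ly <- y[1:(n - 1)]
  sse_u <- sum(resid(lm(dy ~ ly + lx))^2)
  sse_r <- sum(resid(lm(dy ~ ly))^2)
  expect_equal(got$value, log(sse_r / sse_u), tolerance = 1e-10)
  expect_gte(got$value, 0)
  expect_true(got$significant)
  # theoretical value: restricted residual variance 1 + 0.64, unrestricted 1
  expect_lt(abs(got$value - log(1.64)), 0.05)
  # null driver: CGCI near 0, nominal rejection
  set.seed(44)
  rej <- replicate(60, {
    m <- matrix(rnorm(400 * 3), ncol = 3)
    r <- cgci(m, 1, 2, P = 2)
    c(r$value, r$significant)
  })
  expect_lt(mean(rej[1, ]), 0.02)
  expect_lt(mean(rej[2, ]), 0.15)
  expect_gte(min(rej[1, ]), 0)
})

test_that("backward-in-time selection finds active lags and RCGCI follows it", {
  set.seed(45)
  # chain with only lag 2 active: selection must include (x, 2), skip (x, 1)
  hits2 <- hits1 <- 0
  for (r in 1:10) {
    n <- 2000
    x <- rnorm(n)
    y <- c(0, 0, 0.8 * x[1:(n - 2)]) + rnorm(n)
    m <- cbind(x, y)
    sel <- connbench:::bts_select(m, 2, Lmax = 2)
    # exhaustive-BIC oracle over all subsets of the 4 candidates
    cand <- expand.grid(var = 1:2, lag = 1:2)
    rows <- 3:n
    best_bic <- Inf; best_sub <- NULL
    for (mask in 0:15) {
      sub <- cand[bitwAnd(mask, 2^(0:3)) > 0, ]
      sse <- connbench:::ols_sse(m, 2, sub, rows)
      bic <- length(rows) * log(sse / length(rows)) +
        (nrow(sub) + 1) * log(length(rows))
      if (bic < best_bic) { best_bic <- bic; best_sub <- sub }
    }
    in_sel <- paste(sel$var, sel$lag)
    in_best <- paste(best_sub$var, best_sub$lag)
    hits2 <- hits2 + (("1 2" %in% in_sel) && ("1 2" %in% in_best))
    hits1 <- hits1 + (("1 1" %in% in_sel) || !setequal(in_sel, in_best))
  }
  expect_gte(hits2, 9)
  expect_lte(hits1, 2)  # greedy agrees with exhaustive BIC almost always
  # no selected driver terms => statistic exactly 0, not significant
  set.seed(46)
  wn <- matrix(rnorm(1500 * 3), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  r0 <- rcgci(wn, "a", "b", Lmax = 3)
  expect_equal(r0$value, 0)
  expect_false(r0$significant)
  # S2 linear link X4 -> X5 is detected
  p2 <- test_panel("S2", seed = 5)
  expect_true(rcgci(p2, 4, 5, Lmax = 3)$significant)
})

test_that("PDC is column-normalised and calibrated on a diagonal VAR", {
  p2 <- test_panel("S2", seed = 5)
  pd <- suppressWarnings(pdc(p2, P = 3, M = 64))
  # sum_i PDC^2_{j -> i}(f) = 1 at machine precision for every j and f
  s <- apply(pd$pdc^2, c(2, 3), sum)
  expect_lt(max(abs(s - 1)), 1e-12)
  # true linear links stand out at every frequency
  expect_equal(pd$summary$frac_sig[pd$summary$from == "X1" & pd$summary$to == "X3"], 1)
  # diagonal VAR with Gaussian noise: off-diagonal rejection near nominal,
  # under both significance rules
  set.seed(47)
  fracs_a <- fracs_s <- NULL
  for (r in 1:20) {
    n <- 2000
    m <- matrix(0, n, 3)
    e <- matrix(rnorm(3 * n), n, 3)
    for (t in 2:n) m[t, ] <- c(0.5, -0.4, 0.6) * m[t - 1, ] + e[t, ]
    fracs_a <- c(fracs_a, pdc(m, P = 1, M = 32)$summary$frac_sig)
    fracs_s <- c(fracs_s, pdc(m, P = 1, M = 32, test = "schelter")$summary$frac_sig)
  }
  expect_lt(mean(fracs_a), 0.12)
  expect_lt(mean(fracs_s), 0.12)
})
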