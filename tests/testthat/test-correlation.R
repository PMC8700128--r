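test_that("partial Pearson correlation matches formula and residual oracle", {
  set.seed(11)
  # constructed Gaussian triple with rho_xy = rho_xz * rho_zy: partial is 0
  n <- 5e4
  z <- rnorm(n); x <- 0.6 * z + rnorm(n) * 0.8; y <- 0.5 * z + rnorm(n) * sqrt(0.75)
  d <- cbind(x = x, y = y, z = z)
  # single-conditioner recursion formula, computed directly
  rxy <- cor(x, y); rxz <- cor(x, z); rzy <- cor(z, y)
  expected <- (rxy - rxz * rzy) / sqrt((1 - rxz^2) * (1 - rzy^2))
  expect_equal(ppcor(d, "x", "y", cond = "z")$value, expected, tolerance = 1e-12)
  expect_lt(abs(ppcor(d, "x", "y", cond = "z")$value), 0.02)

  # multi-conditioner route equals an explicit residual-regression oracle
  set.seed(12)
  panel <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("V", 1:4)))
  got <- ppcor(panel, 1, 2, cond = c(3, 4))$value
  r1 <- resid(lm(panel[, 1] ~ panel[, 3] + panel[, 4]))
  r2 <- resid(lm(panel[, 2] ~ panel[, 3] + panel[, 4]))
  expect_equal(got, cor(r1, r2), tolerance = 1e-10)
  # symmetric in (i, j)
  expect_equal(got, ppcor(panel, 2, 1, cond = c(3, 4))$value, tolerance = 1e-12)
  # near-copy of a variable: partial correlation ~ 1
  panel2 <- cbind(panel, V5 = panel[, 1] + 1e-8 * rnorm(50))
  expect_gt(ppcor(panel2, 1, 5, cond = c(3, 4))$value, 0.999)
  # singular conditioning set is reported, with the offending column named
  panel3 <- cbind(panel, V5 = panel[, 3])
  expect_error(ppcor(panel3, 1, 2, cond = c(3, 5)), "singular")
})

test_that("partial Spearman correlation is rank-based and monotone-invariant", {
  set.seed(13)
  panel <- matrix(rexp(200), 50, 4, dimnames = list(NULL, paste0("V", 1:4)))
  got <- pspcor(panel, 1, 2)$value
  # definitional oracle: ppcor on rank-transformed columns
  expect_equal(got, ppcor(apply(panel, 2, rank), 1, 2)$value, tolerance = 1e-12)
  # strictly monotone transform of any column leaves the value unchanged
  panel_t <- panel
  panel_t[, 1] <- exp(panel_t[, 1]); panel_t[, 2] <- log(panel_t[, 2] + 1)
  expect_equal(pspcor(panel_t, 1, 2)$value, got, tolerance = 1e-12)
  expect_equal(pspcor(panel, 2, 1)$value, got, tolerance = 1e-12)
})

test_that("KSG mutual information recovers Gaussian closed forms", {
  set.seed(14)
  n <- 20000
  x <- rnorm(n)
  for (rho in c(0, 0.5, 0.9)) {
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    truth <- -0.5 * log(1 - rho^2)
    expect_lt(abs(mi_ksg(x, y, k = 10) - truth), 0.02)
  }
  # independence at moderate n
  expect_lt(abs(mi_ksg(rnorm(5000), rnorm(5000))), 0.02)
  expect_error(mi_ksg(rep(1, 100), rnorm(100)), "constant")
  expect_error(mi_ksg(rnorm(15), rnorm(15), k = 10))
  # symmetry and jitter determinism
  set.seed(15); a <- rnorm(500); b <- a + rnorm(500)
  expect_equal(mi_ksg(a, b), mi_ksg(b, a), tolerance = 1e-12)
  expect_identical(mi_ksg(a, b, jitter_seed = 3), mi_ksg(a, b, jitter_seed = 3))
})

test_that("KSG conditional MI recovers Gaussian partial dependence", {
  set.seed(16)
  n <- 20000
  for (rp in c(0.3, 0.6)) {
    z <- rnorm(n); e1 <- rnorm(n); e2 <- rp * e1 + sqrt(1 - rp^2) * rnorm(n)
    x <- 0.8 * z + e1; y <- 0.8 * z + e2
    truth <- -0.5 * log(1 - rp^2)
    expect_lt(abs(cmi_ksg(x, y, cond = z, k = 10) - truth), 0.03)
  }
  # independent triple
  expect_lt(abs(cmi_ksg(rnorm(5000), rnorm(5000), cond = rnorm(5000))), 0.02)
  # empty conditioning set reduces exactly to plain MI
  set.seed(17); a <- rnorm(800); b <- a^2 + rnorm(800)
  expect_equal(cmi_ksg(a, b), mi_ksg(a, b), tolerance = 1e-12)
})
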