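test_that("noise laws have their closed-form moments and pass KS recovery", {
  laws <- list(
    list(noise_law("gaussian"), mean = 0, var = 1),
    list(noise_law("exponential", rate = 2), mean = 0.5, var = 0.25),
    list(noise_law("chisq", df = 1), mean = 1, var = 2),
    list(noise_law("beta", shape1 = 1, shape2 = 2), mean = 1 / 3, var = 1 / 18),
    list(noise_law("beta", shape1 = 2, shape2 = 1), mean = 2 / 3, var = 1 / 18),
    list(noise_law("gamma", shape = 16, b = 0.25), mean = 4, var = 1)
  )
  for (lw in laws) {
    x <- draw_noise(lw[[1]], 1e5, seed = 99)
    expect_lt(abs(mean(x) - lw$mean), 4 * sqrt(lw$var / 1e5))
    expect_lt(abs(var(x) / lw$var - 1), 0.06)
    ks <- suppressWarnings(ks.test(x[1:1e4], connbench:::noise_cdf(lw[[1]])))
    expect_gt(ks$p.value, 0.01)
  }
  # gamma b as rate is the documented alternative convention
  g <- draw_noise(noise_law("gamma", shape = 16, b = 0.25, b_is_rate = TRUE),
                  1e5, seed = 99)
  expect_lt(abs(mean(g) - 64), 1)
  expect_error(noise_law("weibull"))
})

test_that("identical seeds give bit-identical panels and draws are seed-stable", {
  for (sys in c("S1", "S2", "S3")) {
    a <- simulate_system(sys, n = 300, seed = 7)
    b <- simulate_system(sys, n = 300, seed = 7)
    expect_identical(as.matrix(a), as.matrix(b))
    expect_false(identical(as.matrix(a),
                           as.matrix(simulate_system(sys, n = 300, seed = 8))))
    expect_true(all(is.finite(as.matrix(a))))
    expect_equal(nrow(a), 300)
  }
  # the generator must not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(simulate_system("S2", n = 200, seed = 1)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("printed equation structure is reproduced", {
  # S2: X1 is AR(1) with coefficient 0.7
  p2 <- cached("long_s2", simulate_system("S2", n = 1e5, seed = 3))
  x1 <- p2$X1
  expect_lt(abs(cor(x1[-1], x1[-length(x1)]) - 0.7), 0.02)
  # S1: the linear X2-X3 link is strongly positive and significant
  p1 <- test_panel("S1", seed = 2)
  r <- ppcor(p1, "X2", "X3")
  expect_gt(r$value, 0.5)
  expect_true(r$significant)
  # S3: X5 sits on the 0.5*x3^2 - 3.2 + gamma(16, 0.25) scale, i.e. mean
  # well below the mean-64 noise of the rate reading
  p3 <- test_panel("S3", seed = 2)
  expect_lt(mean(p3$X5), 10)
})

test_that("long runs are stationary and noise streams are independent", {
  p2 <- cached("long_s2", simulate_system("S2", n = 1e5, seed = 3))
  m <- as.matrix(p2)
  h1 <- m[1:5e4, ]; h2 <- m[5e4 + 1:5e4, ]
  expect_true(all(abs(apply(h1, 2, var) / apply(h2, 2, var) - 1) < 0.2))
  # residuals of S2's linear equations reconstruct independent noise streams
  n <- nrow(m)
  e1 <- m[2:n, 1] - 0.7 * m[1:(n - 1), 1]
  e5 <- m[3:n, 5] - 0.5 * m[2:(n - 1), 4] - 0.2 * m[1:(n - 2), 5]
  expect_lt(abs(cor(e1[-1], e5)), 3 / sqrt(n))
  p3 <- cached("long_s3", simulate_system("S3", n = 1e5, seed = 3))
  m3 <- as.matrix(p3)
  expect_true(all(abs(apply(m3[1:5e4, ], 2, var) /
                      apply(m3[5e4 + 1:5e4, ], 2, var) - 1) < 0.2))
})

test_that("truth networks match the known system structure", {
  t1 <- truth_network("S1")
  expect_equal(nrow(t1$contemporaneous), 3)
  expect_equal(nrow(t1$lagged), 0)
  expect_setequal(paste(t1$contemporaneous$i, t1$contemporaneous$j),
                  c("2 3", "1 4", "2 5"))
  t2 <- truth_network("S2")
  expect_equal(nrow(t2$contemporaneous), 0)
  expect_setequal(paste(t2$lagged$from, t2$lagged$to),
                  c("1 2", "1 3", "4 5", "5 4"))
  t3 <- truth_network("S3")
  expect_equal(paste(t3$contemporaneous$i, t3$contemporaneous$j), "1 2")
  expect_setequal(paste(t3$lagged$from, t3$lagged$to),
                  c("2 3", "3 4", "3 5", "1 2"))
  # the lagged X1 -> X2 edge is the equation-implied one
  expect_true(t3$lagged$equation_implied[t3$lagged$from == 1 & t3$lagged$to == 2])
  # no self loops anywhere
  for (tr in list(t1, t2, t3)) {
    expect_true(all(tr$contemporaneous$i != tr$contemporaneous$j))
    expect_true(all(tr$lagged$from != tr$lagged$to))
  }
})
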