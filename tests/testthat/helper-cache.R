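# Shared fixtures: panels and benchmark sweeps are memoised so that
# different test files can reuse the same computations.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache, inherits = FALSE)
}

test_panel <- function(system, n = 2000, seed = 1) {
  cached(paste("panel", system, n, seed, sep = "_"),
         simulate_system(system, n = n, seed = seed))
}

# percentage matrix (and contemporaneous/causal split) for one measure over
# R seeded realizations; base seed fixed for the whole suite
sweep_pct <- function(system, measure, R, n = 2000, base_seed = 4200,
                      settings = benchmark_settings()) {
  key <- paste("sweep", system, measure, R, n, base_seed, sep = "_")
  cached(key, {
    agg <- NULL
    for (r in seq_len(R)) {
      panel <- simulate_system(system, n = n, seed = base_seed + r)
      cell <- suppressWarnings(measure_panel(panel, measure, settings = settings))
      cell$realization <- r
      agg <- rbind(agg, cell)
    }
    stats::aggregate(sig ~ i + j + type, data = agg,
                     FUN = function(s) 100 * mean(s))
  })
}

pct_of <- function(sw, i, j, type = NULL) {
  rows <- sw$i == i & sw$j == j
  if (!is.null(type)) rows <- rows & sw$type == type
  stopifnot(sum(rows) == 1)
  sw$sig[rows]
}

# brute-force double-loop distance covariance / correlation (oracle)
dcov2_brute <- function(x, y) {
  n <- length(x)
  A <- abs(outer(x, x, "-")); B <- abs(outer(y, y, "-"))
  Ac <- matrix(0, n, n); Bc <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    Ac[i, j] <- A[i, j] - mean(A[i, ]) - mean(A[, j]) + mean(A)
    Bc[i, j] <- B[i, j] - mean(B[i, ]) - mean(B[, j]) + mean(B)
  }
  sum(Ac * Bc) / n^2
}

dcor_brute <- function(x, y) {
  v <- dcov2_brute(x, y)
  sqrt(v / sqrt(dcov2_brute(x, x) * dcov2_brute(y, y)))
}

# independent re-derivation of the U-centred partial distance correlation
pdcor_brute <- function(x, y, z) {
  uc <- function(v) {
    D <- as.matrix(dist(v)); n <- nrow(D)
    U <- matrix(0, n, n)
    for (i in 1:n) for (j in 1:n) {
      if (i == j) next
      U[i, j] <- D[i, j] - sum(D[i, ]) / (n - 2) - sum(D[, j]) / (n - 2) +
        sum(D) / ((n - 1) * (n - 2))
    }
    U
  }
  ip <- function(U, V) sum(U * V) / (nrow(U) * (nrow(U) - 3))
  rstar <- function(U, V) {
    d <- sqrt(ip(U, U) * ip(V, V)); if (d <= 0) 0 else ip(U, V) / d
  }
  A <- uc(x); B <- uc(y); C <- uc(z)
  rxy <- rstar(A, B); rxz <- rstar(A, C); rzy <- rstar(C, B)
  den <- sqrt((1 - rxz^2) * (1 - rzy^2))
  if (den <= .Machine$double.eps) 0 else (rxy - rxz * rzy) / den
}
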