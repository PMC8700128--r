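#' Benchmark simulation systems
#'
#' Three five-variate stochastic systems with known connectivity structure:
#'
#' * **S1** — purely contemporaneous, no temporal dynamics. `X1` and `X2` are
#'   i.i.d. exponential and chi-squared noise; `X3`, `X5` are (non)linear
#'   functions of `X2`, and `X4` a nonlinear function of `X1`, each plus
#'   standard Gaussian noise.
#' * **S2** — a nonlinear VAR of order 3 with only lagged (causal) influences:
#'   `X1 -> X2` (quadratic), `X1 -> X3` (linear), `X4 <-> X5` (linear and
#'   nonlinear feedback).
#' * **S3** — both kinds of dependence: a contemporaneous `X1 - X2` link plus
#'   the causal chain `X2 -> X3 -> {X4, X5}`. Substituting the `X1` equation
#'   into `X2`'s shows `X1` also drives `X2` with lag 2, so that lagged edge is
#'   part of the truth network, flagged as equation-implied.
#'
#' Noise laws are used exactly as defined (uncentred): exponential rate 2,
#' chi-squared df 1, beta(1,2)/beta(2,1), and gamma with shape 16 and scale
#' 0.25 (mean 4, variance 1; see `gamma_b_is_rate`).
#'
#' @param id `"S1"`, `"S2"` or `"S3"`.
#' @param gamma_b_is_rate interpret the gamma parameter 0.25 as a rate instead
#'   of a scale (S3 only). The scale reading is the default: the rate reading
#'   gives noise with mean 64 and standard deviation 16, which swamps the
#'   signal paths through `X3`.
#' @return an object of class `"conn_system"`: id, variable count `K`,
#'   labels, largest equation lag `max_lag`, the per-variable noise laws, the
#'   VAR order `P` used by the linear measures, and the truth network.
#' @seealso [simulate_system()], [truth_network()]
#' @export
system_spec <- function(id = c("S1", "S2", "S3"), gamma_b_is_rate = FALSE) {
  id <- match.arg(id)
  K <- 5L
  labels <- paste0("X", 1:K)
  spec <- switch(id,
    S1 = list(
      max_lag = 0L, P = 1L,
      noise = list(noise_law("exponential", rate = 2), noise_law("chisq", df = 1),
                   noise_law("gaussian"), noise_law("gaussian"), noise_law("gaussian")),
      truth = new_truth(contemporaneous = rbind(c(2, 3), c(1, 4), c(2, 5)),
                        lagged = NULL)
    ),
    S2 = list(
      max_lag = 3L, P = 3L,
      noise = list(noise_law("gaussian"), noise_law("exponential", rate = 2),
                   noise_law("beta", shape1 = 1, shape2 = 2),
                   noise_law("beta", shape1 = 2, shape2 = 1), noise_law("gaussian")),
      truth = new_truth(contemporaneous = NULL,
                        lagged = rbind(c(1, 2), c(1, 3), c(4, 5), c(5, 4)))
    ),
    S3 = list(
      max_lag = 3L, P = 3L,
      noise = list(noise_law("gaussian"),
                   noise_law("beta", shape1 = 1, shape2 = 2),
                   noise_law("beta", shape1 = 1, shape2 = 2),
                   noise_law("gaussian"),
                   noise_law("gamma", shape = 16, b = 0.25, b_is_rate = gamma_b_is_rate)),
      truth = new_truth(contemporaneous = rbind(c(1, 2)),
                        lagged = rbind(c(2, 3), c(3, 4), c(3, 5), c(1, 2)),
                        implied = c(FALSE, FALSE, FALSE, TRUE))
    )
  )
  structure(c(list(id = id, K = K, labels = labels,
                   gamma_b_is_rate = gamma_b_is_rate), spec),
            class = "conn_system")
}

new_truth <- function(contemporaneous, lagged, implied = NULL) {
  contem <- if (is.null(contemporaneous)) {
    tibble::tibble(i = integer(), j = integer())
  } else {
    tibble::tibble(i = pmin(contemporaneous[, 1], contemporaneous[, 2]),
                   j = pmax(contemporaneous[, 1], contemporaneous[, 2]))
  }
  lag <- if (is.null(lagged)) {
    tibble::tibble(from = integer(), to = integer(), equation_implied = logical())
  } else {
    tibble::tibble(from = as.integer(lagged[, 1]), to = as.integer(lagged[, 2]),
                   equation_implied = if (is.null(implied)) rep(FALSE, nrow(lagged)) else implied)
  }
  stopifnot(all(contem$i != contem$j), all(lag$from != lag$to),
            !anyDuplicated(paste(contem$i, contem$j)))
  structure(list(contemporaneous = contem, lagged = lag), class = "conn_truth")
}

#' Truth network of a system
#'
#' @param system a [system_spec()] object or a system id string.
#' @return a `"conn_truth"` object: a tibble of unordered contemporaneous
#'   pairs and a tibble of directed lagged edges (self-dependencies are never
#'   part of the truth network).
#' @export
truth_network <- function(system) {
  if (is.character(system)) system <- system_spec(system)
  system$truth
}

#' @export
print.conn_truth <- function(x, ...) {
  cat("<conn_truth> ", nrow(x$contemporaneous), " contemporaneous pair(s), ",
      nrow(x$lagged), " lagged edge(s)\n", sep = "")
  invisible(x)
}

#' Simulate a realization of a benchmark system
#'
#' Generates one seeded realization. For S2/S3 the recursion is started from
#' zeros and a burn-in stretch is discarded so that the retained sample is
#' (approximately) stationary; S1 has no temporal dynamics and needs none.
#' The noise streams of the five variables are mutually independent.
#'
#' @param system a [system_spec()] or id string.
#' @param n sample size after burn-in (>= 100).
#' @param seed integer seed; identical `(system, n, seed)` give bit-identical
#'   panels.
#' @param burn_in points discarded before the retained sample (S2/S3;
#'   default 1000, must be >= the system's largest lag).
#' @return a tibble with `n` rows and columns `X1..X5`, of class
#'   `"conn_panel"`, carrying `system`, `seed`, `burn_in` and the gamma
#'   convention as attributes.
#' @examples
#' p <- simulate_system("S1", n = 500, seed = 1)
#' cor(p$X2, p$X3)  # strong by construction
#' @export
simulate_system <- function(system, n = 2000, seed = 1, burn_in = 1000) {
  if (is.character(system)) system <- system_spec(system)
  stopifnot(inherits(system, "conn_system"))
  if (n < 100) stop("n must be >= 100", call. = FALSE)
  if (system$max_lag == 0L) burn_in <- 0L
  if (burn_in < system$max_lag) stop("burn_in must be >= max_lag", call. = FALSE)

  x <- with_preserved_seed(as.integer(seed), {
    N <- n + burn_in
    e <- vapply(system$noise, draw_noise, numeric(N), m = N)
    gen_system(system$id, e, N)
  })
  if (burn_in > 0) x <- x[(burn_in + 1):(n + burn_in), , drop = FALSE]
  if (any(!is.finite(x)))
    stop("simulation produced non-finite values", call. = FALSE)
  colnames(x) <- system$labels
  out <- tibble::as_tibble(x)
  attr(out, "system") <- system$id
  attr(out, "seed") <- as.integer(seed)
  attr(out, "burn_in") <- as.integer(burn_in)
  attr(out, "gamma_b_is_rate") <- system$gamma_b_is_rate
  class(out) <- c("conn_panel", class(out))
  out
}

gen_system <- function(id, e, N) {
  x <- matrix(0, N, 5)
  if (id == "S1") {
    x[, 1] <- e[, 1]
    x[, 2] <- e[, 2]
    x[, 3] <- 0.8 * x[, 2] + e[, 3]
    x[, 4] <- 0.7 * x[, 1] * (x[, 1]^2 - 1) * exp(-x[, 1]^2 / 2) + e[, 4]
    x[, 5] <- 0.3 * x[, 2] + 0.05 * x[, 2]^2 + e[, 5]
  } else if (id == "S2") {
    for (t in 4:N) {
      x[t, 1] <- 0.7 * x[t - 1, 1] + e[t, 1]
      x[t, 2] <- 0.3 * x[t - 2, 1]^2 + e[t, 2]
      x[t, 3] <- 0.4 * x[t - 3, 1] - 0.3 * x[t - 2, 3] + e[t, 3]
      x[t, 4] <- 0.7 * x[t - 1, 4] - 0.3 * x[t - 1, 5] * exp(-x[t - 1, 5]^2 / 2) + e[t, 4]
      x[t, 5] <- 0.5 * x[t - 1, 4] + 0.2 * x[t - 2, 5] + e[t, 5]
    }
  } else {
    for (t in 4:N) {
      x[t, 1] <- 0.6 * x[t - 2, 1] + e[t, 1]
      x[t, 2] <- x[t, 1] + 0.3 * x[t - 1, 2] + e[t, 2]
      x[t, 3] <- 0.3 * x[t - 1, 3] + sin(x[t - 3, 2]) + e[t, 3]
      x[t, 4] <- 0.4 * x[t - 2, 3] + e[t, 4]
      x[t, 5] <- -3.2 + 0.5 * x[t - 1, 3]^2 + e[t, 5]
    }
  }
  x
}

#' @export
print.conn_panel <- function(x, ...) {
  cat("<conn_panel> system ", attr(x, "system") %||% "?",
      ", n = ", nrow(x), ", seed = ", attr(x, "seed") %||% NA, "\n", sep = "")
  NextMethod()
}
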