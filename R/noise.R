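#' Noise-law descriptors
#'
#' Constructor for the innovation distributions used by the simulation
#' systems: standard Gaussian, exponential, chi-squared, beta, and gamma.
#' Draws are taken exactly from the named law, i.e. they are *not* centred or
#' standardised; several laws therefore have non-zero mean, which is part of
#' the systems' definition.
#'
#' For the gamma family the second parameter `b` is interpreted as the
#' *scale* by default (shape 16, scale 0.25 gives mean 4 and variance 1);
#' set `b_is_rate = TRUE` for the rate reading.
#'
#' @param family one of `"gaussian"`, `"exponential"`, `"chisq"`, `"beta"`,
#'   `"gamma"`.
#' @param ... family parameters: `rate` (exponential), `df` (chisq),
#'   `shape1`/`shape2` (beta), `shape`/`b`/`b_is_rate` (gamma). Gaussian takes
#'   none (standard normal).
#' @return an object of class `"noise_law"`.
#' @examples
#' law <- noise_law("exponential", rate = 2)
#' mean(draw_noise(law, 1e4))  # ~ 0.5
#' @export
noise_law <- function(family, ...) {
  family <- match.arg(family, c("gaussian", "exponential", "chisq", "beta", "gamma"))
  pars <- list(...)
  law <- switch(family,
    gaussian = list(),
    exponential = list(rate = pars$rate %||% 2),
    chisq = list(df = pars$df %||% 1),
    beta = list(shape1 = pars$shape1, shape2 = pars$shape2),
    gamma = list(shape = pars$shape, b = pars$b,
                 b_is_rate = isTRUE(pars$b_is_rate))
  )
  if (family == "beta" && (is.null(law$shape1) || is.null(law$shape2)))
    stop("beta law needs shape1 and shape2", call. = FALSE)
  if (family == "gamma" && (is.null(law$shape) || is.null(law$b)))
    stop("gamma law needs shape and b", call. = FALSE)
  structure(c(list(family = family), law), class = "noise_law")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw i.i.d. noise from a noise law
#'
#' @param law a [noise_law()] descriptor.
#' @param m number of draws.
#' @param seed optional integer; when given, draws are made under this seed
#'   and the caller's RNG state is left untouched.
#' @return numeric vector of length `m`.
#' @export
draw_noise <- function(law, m, seed = NULL) {
  if (!inherits(law, "noise_law")) stop("law must be a noise_law", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  with_preserved_seed(seed, switch(law$family,
    gaussian = rnorm(m),
    exponential = rexp(m, rate = law$rate),
    chisq = rchisq(m, df = law$df),
    beta = rbeta(m, law$shape1, law$shape2),
    gamma = if (law$b_is_rate) rgamma(m, shape = law$shape, rate = law$b)
            else rgamma(m, shape = law$shape, scale = law$b)
  ))
}

# theoretical CDF of a noise law, for distribution-recovery checks
noise_cdf <- function(law) {
  switch(law$family,
    gaussian = stats::pnorm,
    exponential = function(q) stats::pexp(q, rate = law$rate),
    chisq = function(q) stats::pchisq(q, df = law$df),
    beta = function(q) stats::pbeta(q, law$shape1, law$shape2),
    gamma = if (law$b_is_rate) function(q) stats::pgamma(q, shape = law$shape, rate = law$b)
            else function(q) stats::pgamma(q, shape = law$shape, scale = law$b)
  )
}

#' @export
print.noise_law <- function(x, ...) {
  pars <- x[setdiff(names(x), "family")]
  cat("<noise_law> ", x$family,
      if (length(pars)) paste0("(", paste(names(pars), unlist(pars), sep = "=", collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}
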