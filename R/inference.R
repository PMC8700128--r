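#' Parametric t test for a (partial) correlation coefficient
#'
#' Two-sided test of zero correlation based on
#' \eqn{t = r \sqrt{n-2} / \sqrt{1-r^2}} on \eqn{n-2} degrees of freedom.
#' The same degrees of freedom are used for partial correlations (the usual
#' correction subtracts the number of conditioning variables; at the sample
#' sizes this package targets the difference is negligible, and the
#' uncorrected form is the package convention). Set `strict_df = TRUE` to
#' subtract `n_cond`.
#'
#' @param r correlation value, `|r| <= 1`.
#' @param n sample size (> 3).
#' @param alpha significance level.
#' @param n_cond number of conditioning variables (used only when
#'   `strict_df = TRUE`).
#' @param strict_df use `n - 2 - n_cond` degrees of freedom.
#' @return one-row tibble: `statistic` (t), `p_value`, `significant`,
#'   `df`, `method`, `saturated` (`TRUE` when `|r| = 1`, where `p = 0` is
#'   returned by convention).
#' @examples
#' corr_ttest(0.5, 11)  # t = 1.732, p ~ 0.117
#' @export
corr_ttest <- function(r, n, alpha = 0.05, n_cond = 0, strict_df = FALSE) {
  stopifnot(abs(r) <= 1, n > 3)
  df <- n - 2 - if (strict_df) n_cond else 0
  if (abs(r) >= 1) {
    return(tibble::tibble(statistic = Inf * sign(r), p_value = 0,
                          significant = TRUE, df = df, method = "corr_ttest",
                          saturated = TRUE))
  }
  t <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t), df)
  tibble::tibble(statistic = t, p_value = p, significant = p < alpha,
                 df = df, method = "corr_ttest", saturated = FALSE)
}

#' One-sided permutation test by whole-series shuffling
#'
#' Destroys the pairing of `x` with `y` (and any conditioning block) by
#' i.i.d. random permutations of `x` only, recomputes the statistic `B`
#' times, and returns the add-one p-value
#' \eqn{p = (1 + \#\{null \ge observed\}) / (1 + B)}.
#'
#' Note that an i.i.d. shuffle also destroys autocorrelation, so for time
#' series with lagged dependence the test is anti-conservative for
#' contemporaneous-association statistics — this matches common practice for
#' the correlation measures benchmarked here and is part of what the harness
#' is designed to expose.
#'
#' @param stat_fn function `(x, y, ...)` or `(x, y, cond, ...)` returning a
#'   scalar statistic (large = more dependent).
#' @param x,y numeric vectors.
#' @param cond optional conditioning block passed through to `stat_fn`.
#' @param B number of permutations (>= 20).
#' @param alpha significance level.
#' @param seed integer seed for reproducible permutations.
#' @param curtail stop permuting early once the decision at `alpha` can no
#'   longer change (the decision is identical to the full run; the reported
#'   p-value is then computed from the permutations actually drawn).
#' @param ... passed on to `stat_fn`.
#' @return one-row tibble: `statistic`, `p_value`, `significant`, `B_used`,
#'   `method`.
#' @export
permutation_test <- function(stat_fn, x, y, cond = NULL, B = 100,
                             alpha = 0.05, seed = NULL, curtail = FALSE, ...) {
  stopifnot(B >= 20)
  call_stat <- function(xx) {
    if (is.null(cond)) stat_fn(xx, y, ...) else stat_fn(xx, y, cond, ...)
  }
  obs <- call_stat(x)
  limit <- ceiling(alpha * (B + 1))  # once reached, p > alpha is certain
  with_preserved_seed(seed, {
    cnt <- 0L; b <- 0L
    while (b < B) {
      b <- b + 1L
      if (call_stat(sample(x)) >= obs) cnt <- cnt + 1L
      if (curtail && cnt >= limit) break
    }
    p <- (1 + cnt) / (1 + b)
    tibble::tibble(statistic = obs, p_value = p, significant = p <= alpha,
                   B_used = b, method = "permutation")
  })
}

#' F test for nested (restricted vs unrestricted) regressions
#'
#' The Granger-causality significance test used by the VAR-based measures:
#' \eqn{F = ((SSE_R - SSE_U)/q) / (SSE_U / (n_{eff} - p))} on
#' \eqn{(q, n_{eff} - p)} degrees of freedom.
#'
#' @param sse_r,sse_u residual sums of squares of the restricted and
#'   unrestricted fits (`sse_r >= sse_u > 0`).
#' @param q number of restrictions.
#' @param n_eff effective sample size (rows used in the regression).
#' @param p_params number of parameters of the unrestricted model
#'   (including the intercept).
#' @param alpha significance level.
#' @return one-row tibble: `statistic` (F), `p_value`, `significant`, `df1`,
#'   `df2`, `method`.
#' @export
granger_ftest <- function(sse_r, sse_u, q, n_eff, p_params, alpha = 0.05) {
  if (sse_u <= 0 || sse_r < sse_u - 1e-10 * sse_u)
    stop("need sse_r >= sse_u > 0", call. = FALSE)
  df2 <- n_eff - p_params
  if (q <= 0 || df2 <= 0) stop("nonpositive degrees of freedom", call. = FALSE)
  f <- max(0, (sse_r - sse_u) / q) / (sse_u / df2)
  p <- pf(f, q, df2, lower.tail = FALSE)
  tibble::tibble(statistic = f, p_value = p, significant = p < alpha,
                 df1 = q, df2 = df2, method = "granger_ftest")
}
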