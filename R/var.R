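#' Fit a vector autoregression by per-equation least squares
#'
#' Each variable is regressed (with intercept) on the lagged values of all
#' variables up to order `P`, or on an explicit subset of `(variable, lag)`
#' terms. Used by the conditional Granger causality index and partial
#' directed coherence.
#'
#' @param data panel (rows = time, columns = variables).
#' @param P VAR order (>= 1).
#' @param terms optional data frame with columns `var` and `lag` restricting
#'   the regressors of every equation to those terms.
#' @return an object of class `"conn_var"`: coefficient array
#'   `A[K, K, P]` (`A[i, j, r]` is the effect of variable `j` at lag `r` on
#'   variable `i`), intercepts, residual matrix, per-equation residual sums
#'   of squares and variances, effective sample size and the inverse
#'   cross-product of the regressors (used for the parametric PDC test).
#' @examples
#' p <- simulate_system("S2", n = 1000, seed = 1)
#' fit <- fit_var(p, P = 3)
#' round(fit$A[3, 1, 3], 2)  # ~ 0.4 by construction
#' @export
fit_var <- function(data, P, terms = NULL) {
  m <- panel_matrix(data)
  n <- nrow(m); K <- ncol(m)
  if (n <= K * P + 10) stop("need n > K*P + 10", call. = FALSE)
  des <- lag_design(m, P, terms)
  X <- cbind(`(Intercept)` = 1, des$X)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) stop("rank-deficient lag design", call. = FALSE)
  coefs <- qr.coef(qr_, des$Y)
  res <- qr.resid(qr_, des$Y)
  A <- array(0, dim = c(K, K, P),
             dimnames = list(colnames(m), colnames(m), NULL))
  for (r in seq_len(nrow(des$terms))) {
    v <- des$terms$var[r]; l <- des$terms$lag[r]
    A[, v, l] <- coefs[r + 1, ]
  }
  n_eff <- nrow(des$Y)
  sse <- colSums(res^2)
  XtX_inv <- chol2inv(qr.R(qr_))
  dimnames(XtX_inv) <- list(colnames(X), colnames(X))
  structure(list(P = P, K = K, labels = colnames(m), A = A,
                 intercept = coefs[1, ], residuals = res,
                 sse = sse, sigma2 = sse / (n_eff - ncol(X)),
                 Sigma = crossprod(res) / (n_eff - ncol(X)),
                 n_eff = n_eff, n_params = ncol(X),
                 terms = des$terms, XtX_inv = XtX_inv),
            class = "conn_var")
}

#' @export
print.conn_var <- function(x, ...) {
  cat("<conn_var> K =", x$K, " order P =", x$P,
      " terms =", nrow(x$terms), " n_eff =", x$n_eff, "\n")
  invisible(x)
}

# Build response block Y (rows t = maxlag+1 .. n, all K variables) and the
# lagged regressor matrix for the requested (var, lag) terms.
lag_design <- function(m, P, terms = NULL) {
  K <- ncol(m); n <- nrow(m)
  if (is.null(terms))
    terms <- expand.grid(var = seq_len(K), lag = seq_len(P))[
      order(rep(seq_len(P), each = K)), ]
  terms <- tibble::tibble(var = as.integer(terms$var), lag = as.integer(terms$lag))
  maxlag <- max(P, terms$lag)
  rows <- (maxlag + 1):n
  Y <- m[rows, , drop = FALSE]
  X <- matrix(0, length(rows), nrow(terms))
  for (r in seq_len(nrow(terms)))
    X[, r] <- m[rows - terms$lag[r], terms$var[r]]
  colnames(X) <- paste0(colnames(m)[terms$var], ".l", terms$lag)
  list(Y = Y, X = X, terms = terms, rows = rows)
}

# Restricted/unrestricted SSE pair for one target equation, given term sets.
ols_sse <- function(m, target, terms, rows) {
  y <- m[rows, target]
  if (nrow(terms) == 0) {
    X <- matrix(1, length(rows), 1)
  } else {
    X <- matrix(0, length(rows), nrow(terms))
    for (r in seq_len(nrow(terms)))
      X[, r] <- m[rows - terms$lag[r], terms$var[r]]
    X <- cbind(1, X)
  }
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Conditional Granger causality index
#'
#' \eqn{CGCI_{j \to i} = \ln(S_R^2 / S_U^2)}, where \eqn{S_U^2} is the
#' residual variance of the unrestricted VAR(P) equation for target `i`
#' (lags of all variables) and \eqn{S_R^2} that of the restricted equation
#' omitting all lags of the driver `j`. Nonnegative by OLS nesting.
#' Significance is the nested-regression F test with `P` restrictions
#' ([granger_ftest()]).
#'
#' @param data panel.
#' @param src,dst driver and target variables (name or position).
#' @param P VAR order.
#' @param alpha significance level.
#' @return one-row tibble: `from`, `to`, `measure`, `value` (the CGCI),
#'   `statistic` (F), `p_value`, `significant`.
#' @export
cgci <- function(data, src, dst, P, alpha = 0.05) {
  m <- panel_matrix(data)
  jj <- col_index(m, src); ii <- col_index(m, dst)
  if (jj == ii) stop("src and dst must differ", call. = FALSE)
  K <- ncol(m)
  full <- tibble::tibble(var = rep(seq_len(K), P), lag = rep(seq_len(P), each = K))
  rows <- (P + 1):nrow(m)
  sse_u <- ols_sse(m, ii, full, rows)
  sse_r <- ols_sse(m, ii, full[full$var != jj, ], rows)
  ft <- granger_ftest(sse_r, sse_u, q = P, n_eff = length(rows),
                      p_params = K * P + 1, alpha = alpha)
  tibble::tibble(from = colnames(m)[jj], to = colnames(m)[ii], measure = "cgci",
                 value = max(0, log(sse_r / sse_u)), statistic = ft$statistic,
                 p_value = ft$p_value, significant = ft$significant)
}

#' Restricted conditional Granger causality index
#'
#' CGCI computed on a sparse set of lagged terms chosen per target by greedy
#' forward selection with BIC: candidates are all `(variable, lag)` terms
#' with lag at most `Lmax`, examined backward in time (lag 1 of each
#' variable before lag 2, and so on); at each step the term giving the
#' largest BIC improvement enters, and selection stops when no candidate
#' improves BIC. The unrestricted model uses the selected terms; the
#' restricted one drops the driver's selected terms; the F test has as many
#' restrictions as driver terms. When the selection contains no driver
#' terms the index is 0 and not significant.
#'
#' @inheritParams cgci
#' @param Lmax largest candidate lag.
#' @return one-row tibble as [cgci()] (`measure = "rcgci"`; `statistic`/
#'   `p_value` are `NA` when no driver term was selected).
#' @export
rcgci <- function(data, src, dst, Lmax, alpha = 0.05) {
  m <- panel_matrix(data)
  jj <- col_index(m, src); ii <- col_index(m, dst)
  sel <- bts_select(m, ii, Lmax)
  rcgci_from_selection(m, jj, ii, sel, Lmax, alpha)
}

rcgci_from_selection <- function(m, jj, ii, sel, Lmax, alpha) {
  rows <- (Lmax + 1):nrow(m)
  jterms <- sel[sel$var == jj, ]
  if (nrow(jterms) == 0) {
    return(tibble::tibble(from = colnames(m)[jj], to = colnames(m)[ii],
                          measure = "rcgci", value = 0, statistic = NA_real_,
                          p_value = NA_real_, significant = FALSE))
  }
  sse_u <- ols_sse(m, ii, sel, rows)
  sse_r <- ols_sse(m, ii, sel[sel$var != jj, ], rows)
  ft <- granger_ftest(sse_r, sse_u, q = nrow(jterms), n_eff = length(rows),
                      p_params = nrow(sel) + 1, alpha = alpha)
  tibble::tibble(from = colnames(m)[jj], to = colnames(m)[ii], measure = "rcgci",
                 value = max(0, log(sse_r / sse_u)), statistic = ft$statistic,
                 p_value = ft$p_value, significant = ft$significant)
}

# Greedy forward BIC selection of lagged terms for one target equation.
# Candidates are examined lag-1-first per variable; ties break toward the
# smaller lag, then the smaller variable index.
bts_select <- function(m, target, Lmax) {
  K <- ncol(m); n <- nrow(m)
  rows <- (Lmax + 1):n
  n_eff <- length(rows)
  cand <- expand.grid(var = seq_len(K), lag = seq_len(Lmax))
  cand <- cand[order(cand$lag, cand$var), ]
  sel <- tibble::tibble(var = integer(), lag = integer())
  bic <- function(sse, p) n_eff * log(sse / n_eff) + (p + 1) * log(n_eff)
  cur_sse <- ols_sse(m, target, sel, rows)
  cur_bic <- bic(cur_sse, 0)
  repeat {
    if (nrow(cand) == 0) break
    best <- NULL
    for (r in seq_len(nrow(cand))) {
      trial <- rbind(sel, cand[r, ])
      sse <- ols_sse(m, target, trial, rows)
      b <- bic(sse, nrow(trial))
      if (is.null(best) || b < best$bic - 1e-12)
        best <- list(bic = b, row = r)
    }
    if (best$bic >= cur_bic) break
    sel <- rbind(sel, cand[best$row, ])
    cand <- cand[-best$row, ]
    cur_bic <- best$bic
  }
  tibble::tibble(var = as.integer(sel$var), lag = as.integer(sel$lag))
}
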