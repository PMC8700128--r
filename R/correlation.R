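#' Partial Pearson correlation between two panel variables
#'
#' Correlation of `i` and `j` after linearly removing the conditioning
#' variables: computed as the Pearson correlation of the OLS residuals of
#' each variable regressed (with intercept) on `cond`. For a single
#' conditioner this equals the textbook recursion
#' \eqn{\rho_{XY\cdot Z} = (\rho_{XY} - \rho_{XZ}\rho_{ZY}) /
#' \sqrt{(1-\rho_{XZ}^2)(1-\rho_{ZY}^2)}}. Significance is the parametric
#' t test of [corr_ttest()].
#'
#' @param data panel: data frame or matrix, rows = time, columns = variables.
#' @param i,j variable names or positions.
#' @param cond conditioning variables; defaults to all remaining columns.
#'   May be empty (plain correlation).
#' @param alpha significance level.
#' @return one-row tibble: `i`, `j`, `measure`, `value`, `statistic`,
#'   `p_value`, `significant`.
#' @examples
#' p <- simulate_system("S1", n = 500, seed = 1)
#' ppcor(p, "X2", "X3")
#' @export
ppcor <- function(data, i, j, cond = NULL, alpha = 0.05) {
  m <- panel_matrix(data)
  partial_cor_result(m, i, j, cond, alpha, "ppcor")
}

#' Partial Spearman correlation between two panel variables
#'
#' [ppcor()] applied to the column ranks (average ranks on ties), making the
#' measure invariant under strictly monotone marginal transforms.
#'
#' @inheritParams ppcor
#' @return as [ppcor()].
#' @export
pspcor <- function(data, i, j, cond = NULL, alpha = 0.05) {
  m <- apply(panel_matrix(data), 2, rank)
  partial_cor_result(m, i, j, cond, alpha, "pspcor")
}

partial_cor_result <- function(m, i, j, cond, alpha, measure) {
  ii <- col_index(m, i); jj <- col_index(m, j)
  cc <- if (is.null(cond)) setdiff(seq_len(ncol(m)), c(ii, jj)) else col_index(m, cond)
  if (ii == jj) stop("i and j must differ", call. = FALSE)
  n <- nrow(m)
  if (n <= length(cc) + 3) stop("too few rows for conditioning set", call. = FALSE)
  r <- partial_cor(m[, ii], m[, jj], m[, cc, drop = FALSE])
  tt <- corr_ttest(r, n, alpha = alpha)
  tibble::tibble(i = colnames(m)[ii], j = colnames(m)[jj], measure = measure,
                 value = r, statistic = tt$statistic, p_value = tt$p_value,
                 significant = tt$significant)
}

# residual-regression partial correlation; Z may have zero columns
partial_cor <- function(x, y, Z) {
  if (ncol(Z) == 0) return(cor(x, y))
  X <- cbind(1, Z)
  qr_ <- qr(X)
  if (qr_$rank < ncol(X)) {
    bad <- colnames(Z)[qr_$pivot[seq(qr_$rank + 1, ncol(X))] - 1]
    stop("singular conditioning design (columns: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  rx <- qr.resid(qr_, x)
  ry <- qr.resid(qr_, y)
  cor(rx, ry)
}

#' KSG mutual information between two series
#'
#' Kraskov-Stogbauer-Grassberger type-1 estimator with the maximum norm and
#' `k` nearest neighbours, in nats. Estimates can be slightly negative under
#' independence (estimator bias). Ties are broken with a deterministic jitter
#' of amplitude `1e-10` times the column standard deviation, seeded from
#' `jitter_seed`.
#'
#' @param x,y numeric series of equal length (`n > 2k`), non-constant.
#' @param k neighbour count (default 10).
#' @param jitter_seed integer seed for the tie-breaking jitter, or `NULL`
#'   for none.
#' @return MI estimate in nats.
#' @export
mi_ksg <- function(x, y, k = 10, jitter_seed = NULL) {
  stopifnot(length(x) == length(y))
  if (sd(x) == 0 || sd(y) == 0) stop("constant input series", call. = FALSE)
  if (length(x) <= 2 * k) stop("need n > 2k", call. = FALSE)
  m <- add_jitter(cbind(x, y), jitter_seed)
  ksg_cmi_cpp(m[, 1, drop = FALSE], m[, 2, drop = FALSE],
              matrix(numeric(0), length(x), 0), as.integer(k))
}

#' KSG conditional mutual information
#'
#' \eqn{I(X;Y\mid Z)} by the nearest-neighbour estimator (max norm, counts in
#' the `(X,Z)`, `(Y,Z)` and `Z` marginal spaces at the joint-space
#' k-neighbour radius). With an empty conditioning set this reduces exactly
#' to [mi_ksg()].
#'
#' @param x,y numeric series.
#' @param cond conditioning block: vector, matrix or data frame (may be
#'   `NULL`).
#' @inheritParams mi_ksg
#' @return CMI estimate in nats.
#' @export
cmi_ksg <- function(x, y, cond = NULL, k = 10, jitter_seed = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (sd(x) == 0 || sd(y) == 0) stop("constant input series", call. = FALSE)
  if (n <= 2 * k) stop("need n > 2k", call. = FALSE)
  Z <- if (is.null(cond)) matrix(numeric(0), n, 0) else as.matrix(cond)
  m <- add_jitter(cbind(x, y, Z), jitter_seed)
  ksg_cmi_cpp(m[, 1, drop = FALSE], m[, 2, drop = FALSE],
              m[, -(1:2), drop = FALSE], as.integer(k))
}
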