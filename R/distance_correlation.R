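#' Distance correlation of two series
#'
#' Squared-distance-covariance ratio
#' \eqn{dCor^2(X,Y) = dCov^2(X,Y) / \sqrt{dVar(X)\,dVar(Y)}} from
#' double-centred Euclidean distance matrices; the returned value is
#' \eqn{dCor \in [0, 1]}, zero (in population) if and only if X and Y are
#' independent.
#'
#' @param x,y numeric vectors (or matrices of observations in rows) of equal
#'   length, `n >= 4`.
#' @return dCor value in `[0, 1]`.
#' @export
dcor <- function(x, y) {
  A <- dist_mat(x); B <- dist_mat(y)
  n <- nrow(A)
  if (n < 4) stop("need n >= 4", call. = FALSE)
  Ad <- double_center(A); Bd <- double_center(B)
  v2xy <- mean(Ad * Bd)
  v2x <- mean(Ad * Ad); v2y <- mean(Bd * Bd)
  if (v2x <= 0 || v2y <= 0) stop("constant series has zero distance variance", call. = FALSE)
  sqrt(max(0, v2xy / sqrt(v2x * v2y)))
}

dist_mat <- function(x) as.matrix(stats::dist(as.matrix(x)))

double_center <- function(D) {
  rm <- rowMeans(D); gm <- mean(D)
  D - outer(rm, rep(1, ncol(D))) - outer(rep(1, nrow(D)), colMeans(D)) + gm
}

# U-centring of Szekely & Rizzo: unbiased inner-product algebra
u_center <- function(D) {
  n <- nrow(D)
  if (n < 4) stop("U-centring needs n >= 4", call. = FALSE)
  rs <- rowSums(D); cs <- colSums(D); tot <- sum(D)
  U <- D - outer(rs, rep(1, n)) / (n - 2) - outer(rep(1, n), cs) / (n - 2) +
    tot / ((n - 1) * (n - 2))
  diag(U) <- 0
  U
}

u_inner <- function(U, V) {
  n <- nrow(U)
  sum(U * V) / (n * (n - 3))
}

# bias-corrected distance correlation from U-centred matrices
bcd_cor <- function(U, V) {
  num <- u_inner(U, V)
  den <- sqrt(u_inner(U, U) * u_inner(V, V))
  if (den <= 0) 0 else num / den
}

#' Partial distance correlation
#'
#' Partial distance correlation of panel variables `i` and `j` given the
#' conditioning set, via the Hilbert-space construction on *U-centred*
#' (bias-corrected) distance matrices: the U-centred matrices of `i` and `j`
#' are projected orthogonally to that of the conditioning block (all
#' conditioning columns stacked into one Euclidean space), and the cosine of
#' the projections is returned. With an empty conditioning set this is the
#' bias-corrected distance correlation. Set `ucenter = FALSE` for the plain
#' double-centred variant (useful for cross-checks; biased).
#'
#' Significance, when requested, is a one-sided permutation test
#' ([permutation_test()]) with `B` shuffles of variable `i`.
#'
#' @inheritParams ppcor
#' @param ucenter use the unbiased U-centred algebra (default).
#' @param B permutations for the significance test; `0` skips the test.
#' @param seed seed for the permutation test.
#' @return one-row tibble as [ppcor()] (with `p_value = NA` when `B = 0`).
#' @export
pdcor <- function(data, i, j, cond = NULL, alpha = 0.05, ucenter = TRUE,
                  B = 0, seed = NULL) {
  m <- panel_matrix(data)
  ii <- col_index(m, i); jj <- col_index(m, j)
  cc <- if (is.null(cond)) setdiff(seq_len(ncol(m)), c(ii, jj)) else col_index(m, cond)
  if (nrow(m) < 10) stop("need n >= 10", call. = FALSE)
  x <- m[, ii]; y <- m[, jj]; z <- m[, cc, drop = FALSE]
  val <- pdcor_stat(x, y, z, ucenter)
  p <- NA_real_; sig <- NA
  if (B > 0) {
    pt <- permutation_test(function(xx, yy, zz) pdcor_stat(xx, yy, zz, ucenter),
                           x, y, cond = z, B = B, alpha = alpha, seed = seed)
    p <- pt$p_value; sig <- pt$significant
  }
  tibble::tibble(i = colnames(m)[ii], j = colnames(m)[jj], measure = "pdcor",
                 value = val, statistic = val, p_value = p, significant = sig)
}

pdcor_stat <- function(x, y, z, ucenter = TRUE) {
  cen <- if (ucenter) u_center else double_center
  corf <- if (ucenter) {
    bcd_cor
  } else {
    function(U, V) {
      den <- sqrt(mean(U * U) * mean(V * V))
      if (den <= 0) 0 else mean(U * V) / den
    }
  }
  A <- cen(dist_mat(x)); B <- cen(dist_mat(y))
  if (NCOL(z) == 0 || length(z) == 0) {
    r <- corf(A, B)
    return(if (ucenter) r else sqrt(max(0, r)))
  }
  C <- cen(dist_mat(z))
  rxy <- corf(A, B); rxz <- corf(A, C); rzy <- corf(C, B)
  den <- sqrt((1 - rxz^2) * (1 - rzy^2))
  if (den <= .Machine$double.eps) return(0)
  (rxy - rxz * rzy) / den
}
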