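#' Build a mixed (non-uniform) embedding for one target variable
#'
#' Greedy, surrogate-gated selection of the lagged (and optionally
#' contemporaneous) terms that best explain the target's next value
#' \eqn{x_{i,t+1}}. Candidates are all `(variable, lag)` pairs with lag in
#' `1..Lmax` for every variable, plus lag-0 terms \eqn{x_{v,t+1}} of the
#' other variables in zero-lag mode. Each cycle picks the candidate with the
#' largest KSG conditional mutual information given the terms already
#' selected, then tests it against `n_surrogates` random circular
#' time-shifts of the candidate column (minimum shift 20, preserving the
#' candidate's marginal autocorrelation): the term is accepted only when the
#' observed CMI exceeds the \eqn{(1-\alpha)} quantile of the surrogate CMIs.
#' Selection stops at the first rejection.
#'
#' @param data panel.
#' @param target target variable (name or position).
#' @param Lmax largest candidate lag (>= 1).
#' @param mode `"lagged"` (lags `1..Lmax` only) or `"zero"` (additionally
#'   lag-0 terms of the other variables, taken simultaneous with the
#'   predicted sample; see `zero_lag_at`).
#' @param k KSG neighbour count.
#' @param n_surrogates surrogate count for the acceptance test.
#' @param alpha termination significance level.
#' @param seed seed for the surrogate shifts (and tie-breaking jitter);
#'   defaults to the panel's generation seed when present.
#' @param zero_lag_at `"t+1"` (default: lag-0 means \eqn{x_{v,t+1}},
#'   simultaneous with the response) or `"t"`.
#' @return an object of class `"conn_embedding"`: tibble `terms` with
#'   columns `var`, `lag`, `cmi` (acceptance value), plus the aligned
#'   response/term matrix used, for downstream statistics.
#' @export
build_embedding <- function(data, target, Lmax = 4, mode = c("lagged", "zero"),
                            k = 10, n_surrogates = 100, alpha = 0.05,
                            seed = NULL, zero_lag_at = c("t+1", "t")) {
  mode <- match.arg(mode)
  zero_lag_at <- match.arg(zero_lag_at)
  m <- panel_matrix(data)
  if (is.null(seed)) seed <- panel_seed(data)
  K <- ncol(m); n <- nrow(m)
  ii <- col_index(m, target)
  stopifnot(Lmax >= 1)

  # alignment: response is x_{i,t+1} for t+1 = (Lmax+1)..n
  rows <- (Lmax + 1):n
  y <- m[rows, ii]
  cand <- expand.grid(var = seq_len(K), lag = seq_len(Lmax))
  if (mode == "zero")
    cand <- rbind(expand.grid(var = setdiff(seq_len(K), ii), lag = 0L), cand)
  cand_col <- function(v, l) {
    if (l == 0 && zero_lag_at == "t+1") m[rows, v] else m[rows - max(l, 1) + (l == 0), v]
  }
  # (for zero_lag_at = "t": lag-0 uses rows - 1 + 1 = rows ... see below)
  Xc <- vapply(seq_len(nrow(cand)),
               function(r) cand_col(cand$var[r], cand$lag[r]), numeric(length(y)))
  if (zero_lag_at == "t") {
    z0 <- which(cand$lag == 0L)
    for (r in z0) Xc[, r] <- m[rows - 1, cand$var[r]]
  }

  mlen <- length(y)
  min_shift <- 20
  sel <- integer(0)
  cmis <- numeric(0)
  with_preserved_seed(seed, {
    repeat {
      remaining <- setdiff(seq_len(nrow(cand)), sel)
      if (length(remaining) == 0) break
      W <- if (length(sel)) Xc[, sel, drop = FALSE] else NULL
      vals <- vapply(remaining, function(r) {
        cmi_ksg(Xc[, r], y, cond = W, k = k)
      }, numeric(1))
      best <- remaining[which.max(vals)]
      obs <- max(vals)
      shifts <- min_shift + floor(runif(n_surrogates) * (mlen - 2 * min_shift + 1))
      # acceptance needs obs to exceed the (1-alpha) surrogate quantile; the
      # loop stops as soon as enough surrogates beat obs to settle rejection
      reject_at <- n_surrogates - ceiling((1 - alpha) * n_surrogates) + 1
      cnt <- 0L
      for (s in shifts) {
        xs <- Xc[c((s + 1):mlen, 1:s), best]
        if (cmi_ksg(xs, y, cond = W, k = k) >= obs) cnt <- cnt + 1L
        if (cnt >= reject_at) break
      }
      if (cnt >= reject_at) break
      sel <- c(sel, best)
      cmis <- c(cmis, obs)
    }
  })
  terms <- tibble::tibble(var = as.integer(cand$var[sel]),
                          lag = as.integer(cand$lag[sel]), cmi = cmis)
  structure(list(target = ii, labels = colnames(m), terms = terms,
                 y = y, X = if (length(sel)) Xc[, sel, drop = FALSE] else
                   matrix(numeric(0), mlen, 0),
                 Lmax = Lmax, mode = mode, k = k, alpha = alpha,
                 n_surrogates = n_surrogates, seed = seed),
            class = "conn_embedding")
}

#' @export
print.conn_embedding <- function(x, ...) {
  cat("<conn_embedding> target ", x$labels[x$target], " (", x$mode,
      " mode): ", nrow(x$terms), " term(s)\n", sep = "")
  if (nrow(x$terms))
    print(tibble::tibble(term = paste0(x$labels[x$terms$var],
                                       "(t-", x$terms$lag, ")"),
                         cmi = x$terms$cmi))
  invisible(x)
}

#' Partial transfer entropy on non-uniform embedding
#'
#' Builds the lagged-only mixed embedding for the target (shared across all
#' drivers) and reports, for driver `j`,
#' \eqn{I(x_{i,t+1}; w^j \mid w \setminus w^j)} where \eqn{w^j} are the
#' selected terms of `j`. Because the embedding terms were individually
#' accepted against time-shift surrogates, a positive statistic itself
#' indicates a causal effect and no outer significance test is applied; the
#' statistic is exactly 0 (not significant) when no terms of `j` were
#' selected.
#'
#' @inheritParams build_embedding
#' @param src,dst driver and target.
#' @param alpha termination level (0.01 by convention for this measure).
#' @return one-row tibble: `from`, `to`, `measure`, `value`, `significant`.
#' @export
ptenue <- function(data, src, dst, Lmax = 4, k = 10, n_surrogates = 100,
                   alpha = 0.01, seed = NULL) {
  emb <- build_embedding(data, dst, Lmax = Lmax, mode = "lagged", k = k,
                         n_surrogates = n_surrogates, alpha = alpha, seed = seed)
  ptenue_from_embedding(emb, src)
}

ptenue_from_embedding <- function(emb, src) {
  m_src <- col_index_lab(emb$labels, src)
  jdx <- which(emb$terms$var == m_src)
  val <- 0
  if (length(jdx) > 0) {
    Wj <- emb$X[, jdx, drop = FALSE]
    Wrest <- emb$X[, -jdx, drop = FALSE]
    val <- group_cmi(emb$y, Wj, Wrest, emb$k)
    val <- max(0, val)
  }
  tibble::tibble(from = emb$labels[m_src], to = emb$labels[emb$target],
                 measure = "ptenue", value = val,
                 significant = val > 0 & length(jdx) > 0)
}

col_index_lab <- function(labels, v) {
  if (is.character(v)) match(v, labels) else as.integer(v)
}

# I(y; A | B) with multi-column groups (B may have zero columns)
group_cmi <- function(y, A, B, k) {
  ksg_cmi_cpp(A, matrix(y), B, as.integer(k))
}

#' Partial mutual information on mixed embedding with zero-lag terms
#'
#' Builds the with-zero-lag embedding for the target and reports, for driver
#' `j`, two normalised statistics: the *lagged* contribution
#' \deqn{R_{lag} = I(x_{i,t+1}; w^j_{\ell \ge 1} \mid w \setminus
#'   w^j_{\ell \ge 1}) / I(x_{i,t+1}; w)}
#' and the *contemporaneous* contribution computed likewise from `j`'s
#' lag-0 term. Each is reported significant when positive; both are exactly
#' 0 when the embedding holds no such terms. When the total information
#' \eqn{I(x_{i,t+1}; w)} is not positive both statistics are reported 0
#' with a warning.
#'
#' @inheritParams ptenue
#' @param alpha termination level (0.05 by convention for this measure).
#' @return tibble with two rows (`type` = `"contemporaneous"`, `"causal"`):
#'   `from`, `to`, `measure`, `type`, `value`, `significant`.
#' @export
pmime0 <- function(data, src, dst, Lmax = 4, k = 10, n_surrogates = 100,
                   alpha = 0.05, seed = NULL) {
  emb <- build_embedding(data, dst, Lmax = Lmax, mode = "zero", k = k,
                         n_surrogates = n_surrogates, alpha = alpha, seed = seed)
  pmime0_from_embedding(emb, src)
}

pmime0_from_embedding <- function(emb, src) {
  m_src <- col_index_lab(emb$labels, src)
  lag_idx <- which(emb$terms$var == m_src & emb$terms$lag >= 1)
  con_idx <- which(emb$terms$var == m_src & emb$terms$lag == 0)
  rlag <- rcon <- 0
  if (nrow(emb$terms) > 0 && (length(lag_idx) || length(con_idx))) {
    tot <- group_cmi(emb$y, emb$X, matrix(numeric(0), length(emb$y), 0), emb$k)
    if (tot <= 0) {
      warning("total embedding information is not positive; reporting zeros")
    } else {
      if (length(lag_idx))
        rlag <- max(0, group_cmi(emb$y, emb$X[, lag_idx, drop = FALSE],
                                 emb$X[, -lag_idx, drop = FALSE], emb$k)) / tot
      if (length(con_idx))
        rcon <- max(0, group_cmi(emb$y, emb$X[, con_idx, drop = FALSE],
                                 emb$X[, -con_idx, drop = FALSE], emb$k)) / tot
    }
  }
  tibble::tibble(from = emb$labels[m_src], to = emb$labels[emb$target],
                 measure = "pmime0",
                 type = c("contemporaneous", "causal"),
                 value = c(rcon, rlag),
                 significant = c(rcon > 0, rlag > 0))
}
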