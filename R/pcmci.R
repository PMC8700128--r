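#' Conditional independence test between lagged panel variables
#'
#' Tests \eqn{x_{j,t-\tau_x} \perp x_{i,t-\tau_y} \mid} a set of lagged
#' conditioning terms, with either a partial-correlation t test
#' (`method = "parcorr"`) or the KSG conditional-mutual-information
#' statistic with a local-permutation null (`method = "cmi_knn"`): the
#' driver column is permuted within KNN neighbourhoods of the conditioning
#' values (`k_perm` neighbours), which preserves its relation to the
#' conditioning set while destroying any conditional association, and a
#' one-sided add-one p-value is computed from `B` permutations.
#'
#' @param data panel.
#' @param x,y terms, each `c(variable, lag)` (lag >= 0, counted backwards
#'   from the reference time).
#' @param cond list of conditioning terms in the same format (may be empty).
#' @param method `"parcorr"` or `"cmi_knn"`.
#' @param alpha significance level.
#' @param k KSG neighbour count; `k_perm` local-permutation neighbourhood.
#' @param B permutations for the `cmi_knn` null.
#' @param seed RNG seed for the permutation null.
#' @param curtail allow early stopping of the permutation loop once the
#'   decision at `alpha` is settled (decision identical to the full run).
#' @return one-row tibble: `statistic`, `p_value`, `independent` (at
#'   `alpha`), `method`, `n_eff`.
#' @export
ci_test <- function(data, x, y, cond = list(), method = c("parcorr", "cmi_knn"),
                    alpha = 0.05, k = 10, k_perm = 5, B = 100, seed = NULL,
                    curtail = FALSE) {
  method <- match.arg(method)
  m <- panel_matrix(data)
  al <- align_terms(m, c(list(x, y), cond))
  if (nrow(al) == 0) stop("empty aligned sample", call. = FALSE)
  ci_test_aligned(al[, 1], al[, 2], al[, -(1:2), drop = FALSE], method,
                  alpha, k, k_perm, B, seed, curtail)
}

# align a list of (var, lag) terms into columns over the common time window
align_terms <- function(m, terms) {
  lags <- vapply(terms, function(t) as.integer(t[2]), integer(1))
  maxlag <- max(lags)
  rows <- (maxlag + 1):nrow(m)
  out <- vapply(terms, function(t) m[rows - as.integer(t[2]), as.integer(t[1])],
                numeric(length(rows)))
  out
}

ci_test_aligned <- function(xv, yv, Z, method, alpha, k, k_perm, B, seed,
                            curtail = FALSE) {
  n <- length(xv)
  if (method == "parcorr") {
    r <- partial_cor(xv, yv, Z)
    tt <- corr_ttest(r, n, alpha = alpha, n_cond = ncol(Z), strict_df = TRUE)
    return(tibble::tibble(statistic = r, p_value = tt$p_value,
                          independent = !tt$significant, method = "parcorr",
                          n_eff = n))
  }
  obs <- cmi_ksg(xv, yv, cond = if (ncol(Z)) Z else NULL, k = k)
  limit <- ceiling(alpha * (B + 1))
  res <- with_preserved_seed(seed, {
    nb <- if (ncol(Z)) knn_indices_cpp(Z, as.integer(min(k_perm, n - 1))) else NULL
    cnt <- 0L; b <- 0L
    while (b < B) {
      b <- b + 1L
      xp <- local_permute(xv, nb)
      v <- cmi_ksg(xp, yv, cond = if (ncol(Z)) Z else NULL, k = k)
      if (v >= obs) cnt <- cnt + 1L
      if (curtail && cnt >= limit) break
    }
    list(p = (1 + cnt) / (1 + b))
  })
  tibble::tibble(statistic = obs, p_value = res$p,
                 independent = res$p > alpha, method = "cmi_knn", n_eff = n)
}

# Permute x within KNN neighbourhoods of the conditioning values; with no
# conditioning this is a plain shuffle. Each value is used at most once.
local_permute <- function(x, nb) {
  n <- length(x)
  if (is.null(nb)) return(sample(x))
  ord <- sample.int(n)
  used <- logical(n)
  out <- numeric(n)
  for (i in ord) {
    cands <- nb[i, sample.int(ncol(nb))]
    pick <- 0L
    for (j in cands) if (!used[j]) { pick <- j; break }
    if (pick == 0L) {
      free <- which(!used)
      pick <- if (length(free) == 1) free else sample(free, 1)
    }
    out[i] <- x[pick]
    used[pick] <- TRUE
  }
  out
}

#' Lagged and contemporaneous causal discovery (PCMCI+ style)
#'
#' Two-phase constraint-based discovery over a time-series panel:
#'
#' 1. **Lagged parent pre-selection** per target (PC1-style): all
#'    `(variable, lag)` candidates with lag `1..tau_max` are iteratively
#'    pruned by CI tests conditioned on the `q` currently strongest other
#'    candidates, with `q` increasing until it exhausts the surviving set.
#' 2. **Momentary CI tests**: every lagged link `j (lag tau) -> i` is tested
#'    given the discovered parents of `i` (minus the link itself) plus the
#'    parents of `j` shifted by `tau`; every contemporaneous pair is tested
#'    once given both endpoints' parents.
#'
#' Contemporaneous links are then oriented by collider detection on
#' unshielded triples with a majority vote over conditioning subsets (up to
#' size 2) of the adjacent contemporaneous neighbours; triples with a tied
#' or conflicting vote stay unoriented, and unoriented links are scored in
#' both directions by the benchmark harness.
#'
#' @param data panel.
#' @param tau_max largest lag considered (>= 1).
#' @param alpha significance level (also used for phase-1 pruning).
#' @param method CI test: `"parcorr"` or `"cmi_knn"` (see [ci_test()]).
#' @param k,k_perm,B `cmi_knn` settings.
#' @param seed RNG seed (permutation nulls).
#' @param curtail early-stop permutation loops (identical decisions).
#' @param max_conds cap on the number of (strongest) parents used as
#'   conditions in the momentary-CI phase; `Inf` (default) uses all
#'   discovered parents. Smaller values trade fidelity for speed.
#' @return an object of class `"conn_graph"`: `lagged` tibble
#'   (`from`, `to`, `tau`, `statistic`, `p_value`), `contemporaneous` tibble
#'   (`i`, `j`, `orientation` in `"i->j"`, `"j->i"`, `"undirected"`), and
#'   the per-target lagged parent sets.
#' @export
pcmci_plus <- function(data, tau_max = 4, alpha = 0.05,
                       method = c("parcorr", "cmi_knn"), k = 10, k_perm = 5,
                       B = 100, seed = NULL, curtail = TRUE, max_conds = Inf) {
  method <- match.arg(method)
  m <- panel_matrix(data)
  if (is.null(seed)) seed <- panel_seed(data) %||% 1L
  K <- ncol(m)
  stopifnot(tau_max >= 1)
  test_idx <- 0L
  run_test <- function(x, y, cond) {
    test_idx <<- test_idx + 1L
    # drop duplicate conditioning terms and any term equal to x or y
    if (length(cond)) {
      key <- vapply(cond, paste, character(1), collapse = "_")
      keep <- !duplicated(key) & key != paste(x, collapse = "_") &
        key != paste(y, collapse = "_")
      cond <- cond[keep]
    }
    al <- align_terms(m, c(list(x, y), cond))
    ci_test_aligned(al[, 1], al[, 2], al[, -(1:2), drop = FALSE], method,
                    alpha, k, k_perm, B, seed = seed + test_idx,
                    curtail = curtail)
  }

  # ---- phase 1: lagged parent supersets per target
  parents <- vector("list", K)
  for (i in seq_len(K)) {
    cand <- expand.grid(var = seq_len(K), lag = seq_len(tau_max))
    stat <- rep(NA_real_, nrow(cand))
    keep <- rep(TRUE, nrow(cand))
    q <- 0L
    repeat {
      changed <- FALSE
      ord <- order(-abs(stat), na.last = TRUE)
      for (r in which(keep)) {
        others <- setdiff(ord[keep[ord]], r)
        if (length(others) < q && q > 0) next
        condset <- lapply(head(others, q), function(s) c(cand$var[s], cand$lag[s]))
        res <- run_test(c(cand$var[r], cand$lag[r]), c(i, 0L), condset)
        stat[r] <- abs(res$statistic)
        if (res$independent) { keep[r] <- FALSE; changed <- TRUE }
      }
      q <- q + 1L
      if (q > sum(keep) - 1L) break
      if (!any(keep)) break
    }
    pk <- cand[keep, , drop = FALSE]
    pk$stat <- stat[keep]
    parents[[i]] <- pk[order(-abs(pk$stat)), , drop = FALSE]
  }
  top_parents <- function(p, drop_var = NULL, drop_lag = NULL) {
    if (!is.null(drop_var)) p <- p[!(p$var == drop_var & p$lag == drop_lag), , drop = FALSE]
    head(p, max_conds)
  }

  # ---- phase 2: momentary CI tests
  lag_edges <- NULL
  for (i in seq_len(K)) for (j in seq_len(K)) for (tau in seq_len(tau_max)) {
    pi_ <- top_parents(parents[[i]], j, tau)
    cond <- lapply(seq_len(nrow(pi_)), function(r) c(pi_$var[r], pi_$lag[r]))
    pj <- top_parents(parents[[j]])
    cond <- c(cond, lapply(seq_len(nrow(pj)),
                           function(r) c(pj$var[r], pj$lag[r] + tau)))
    res <- run_test(c(j, tau), c(i, 0L), cond)
    if (!res$independent)
      lag_edges <- rbind(lag_edges,
                         data.frame(from = j, to = i, tau = tau,
                                    statistic = res$statistic,
                                    p_value = res$p_value))
  }
  lag_edges <- if (is.null(lag_edges)) {
    tibble::tibble(from = integer(), to = integer(), tau = integer(),
                   statistic = numeric(), p_value = numeric())
  } else tibble::as_tibble(lag_edges)

  contem <- NULL
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    pi_ <- top_parents(parents[[i]]); pj <- top_parents(parents[[j]])
    cond <- c(lapply(seq_len(nrow(pi_)), function(r) c(pi_$var[r], pi_$lag[r])),
              lapply(seq_len(nrow(pj)), function(r) c(pj$var[r], pj$lag[r])))
    res <- run_test(c(j, 0L), c(i, 0L), cond)
    if (!res$independent)
      contem <- rbind(contem, data.frame(i = i, j = j,
                                         statistic = res$statistic,
                                         p_value = res$p_value))
  }
  contem <- if (is.null(contem)) {
    tibble::tibble(i = integer(), j = integer(),
                   statistic = numeric(), p_value = numeric())
  } else tibble::as_tibble(contem)
  contem$orientation <- rep("undirected", nrow(contem))

  # ---- contemporaneous orientation: collider majority rule
  if (nrow(contem) >= 2) {
    adj <- lapply(seq_len(K), function(v)
      sort(unique(c(contem$j[contem$i == v], contem$i[contem$j == v]))))
    orient <- matrix(0L, K, K)  # +1 votes for v -> k
    for (kmid in seq_len(K)) {
      nbs <- adj[[kmid]]
      if (length(nbs) < 2) next
      prs <- utils::combn(nbs, 2)
      for (c_ in seq_len(ncol(prs))) {
        a <- prs[1, c_]; b <- prs[2, c_]
        if (b %in% adj[[a]]) next  # shielded
        pool <- setdiff(union(adj[[a]], adj[[b]]), c(a, b))
        subsets <- list(integer(0))
        for (s in pool) subsets <- c(subsets, list(s))
        if (length(pool) >= 2) {
          two <- utils::combn(pool, 2)
          for (c2 in seq_len(ncol(two))) subsets <- c(subsets, list(two[, c2]))
        }
        pa <- top_parents(parents[[a]]); pb <- top_parents(parents[[b]])
        base <- c(lapply(seq_len(nrow(pa)), function(r) c(pa$var[r], pa$lag[r])),
                  lapply(seq_len(nrow(pb)), function(r) c(pb$var[r], pb$lag[r])))
        sep_with <- 0L; sep_without <- 0L
        for (S in subsets) {
          cond <- c(base, lapply(S, function(v) c(v, 0L)))
          res <- run_test(c(a, 0L), c(b, 0L), cond)
          if (res$independent) {
            if (kmid %in% S) sep_with <- sep_with + 1L else sep_without <- sep_without + 1L
          }
        }
        if (sep_with + sep_without == 0) next
        if (sep_without > sep_with) {  # majority: kmid not needed to separate -> collider
          orient[a, kmid] <- orient[a, kmid] + 1L
          orient[b, kmid] <- orient[b, kmid] + 1L
        }
      }
    }
    for (r in seq_len(nrow(contem))) {
      i <- contem$i[r]; j <- contem$j[r]
      to_j <- orient[i, j] > 0; to_i <- orient[j, i] > 0
      contem$orientation[r] <-
        if (to_j && !to_i) "i->j" else if (to_i && !to_j) "j->i" else "undirected"
    }
  }

  structure(list(labels = colnames(m), K = K, tau_max = tau_max,
                 alpha = alpha, method = method,
                 lagged = lag_edges, contemporaneous = contem,
                 parents = parents, n_tests = test_idx),
            class = "conn_graph")
}

#' @export
print.conn_graph <- function(x, ...) {
  cat("<conn_graph> ", nrow(x$lagged), " lagged link(s), ",
      nrow(x$contemporaneous), " contemporaneous link(s) [",
      x$method, ", tau_max = ", x$tau_max, "]\n", sep = "")
  invisible(x)
}
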