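#' Default benchmark settings
#'
#' The estimator settings used for the percentage tables: VAR order per
#' system (1 for S1, 3 for S2/S3), `Lmax = 4` and `k = 10` for the
#' information measures, 100 permutations/surrogates, 256 PDC frequencies,
#' `tau_max = 4` for causal discovery, significance level 0.05 everywhere
#' except the transfer-entropy embedding termination (0.01).
#'
#' @param ... overrides of the defaults.
#' @return named list of settings.
#' @export
benchmark_settings <- function(...) {
  s <- list(P = c(S1 = 1L, S2 = 3L, S3 = 3L), Lmax = 4L, k = 10L, k_perm = 5L,
            B = 100L, alpha = 0.05, alpha_ptenue = 0.01, n_freq = 256L,
            tau_max = 4L, curtail = TRUE, max_conds = Inf)
  ov <- list(...)
  s[names(ov)] <- ov
  s
}

symmetric_measures <- c("ppcor", "pspcor", "pdcor", "mi")
directional_measures <- c("cgci", "rcgci", "pdc", "ptenue")
instantaneous_measures <- c("pmime0", "pcmci")

#' Compute one connectivity measure on one panel
#'
#' The per-realization work unit of [run_benchmark()]: evaluates the
#' requested measure for every unordered (symmetric measures) or ordered
#' pair and returns a tidy significance table.
#'
#' @param panel a panel (ideally from [simulate_system()], so that the
#'   system id and seed are carried along).
#' @param measure one of `"ppcor"`, `"pspcor"`, `"pdcor"`, `"mi"`,
#'   `"cgci"`, `"rcgci"`, `"pdc"`, `"ptenue"`, `"pmime0"`, `"pcmci"`.
#' @param settings a [benchmark_settings()] list.
#' @param P VAR order override (otherwise taken from the panel's system id).
#' @param seed seed for permutation/surrogate randomness (defaults to the
#'   panel seed).
#' @return tibble with columns `i`, `j` (variable positions; `i` drives `j`
#'   for directional rows), `type` (`"contemporaneous"` or `"causal"`),
#'   `value`, and `sig` (0/1, or a fraction in `[0,1]` for PDC, whose
#'   aggregate is defined over frequencies as well as realizations).
#' @export
measure_panel <- function(panel, measure, settings = benchmark_settings(),
                          P = NULL, seed = NULL) {
  measure <- match.arg(measure, c(symmetric_measures, directional_measures,
                                  instantaneous_measures))
  m <- panel_matrix(panel)
  K <- ncol(m)
  if (is.null(seed)) seed <- panel_seed(panel) %||% 1L
  if (is.null(P)) {
    sys_id <- attr(panel, "system", exact = TRUE)
    P <- if (!is.null(sys_id) && sys_id %in% names(settings$P))
      settings$P[[sys_id]] else 3L
  }
  pairs_sym <- which(upper.tri(matrix(0, K, K)), arr.ind = TRUE)
  pairs_dir <- expand.grid(i = seq_len(K), j = seq_len(K))
  pairs_dir <- pairs_dir[pairs_dir$i != pairs_dir$j, ]

  sym_result <- function(f) {
    out <- lapply(seq_len(nrow(pairs_sym)), function(r) {
      f(pairs_sym[r, 1], pairs_sym[r, 2])
    })
    tibble::tibble(i = pairs_sym[, 1], j = pairs_sym[, 2],
                   type = "contemporaneous",
                   value = vapply(out, `[[`, numeric(1), 1),
                   sig = vapply(out, `[[`, numeric(1), 2))
  }

  switch(measure,
    ppcor = sym_result(function(i, j) {
      r <- ppcor(m, i, j, alpha = settings$alpha)
      c(r$value, as.numeric(r$significant))
    }),
    pspcor = sym_result(function(i, j) {
      r <- pspcor(m, i, j, alpha = settings$alpha)
      c(r$value, as.numeric(r$significant))
    }),
    pdcor = sym_result(function(i, j) {
      r <- pdcor(m, i, j, alpha = settings$alpha, B = settings$B,
                 seed = seed + 1000L * i + j)
      c(r$value, as.numeric(r$significant))
    }),
    mi = sym_result(function(i, j) {
      pt <- permutation_test(function(x, y) mi_ksg(x, y, k = settings$k),
                             m[, i], m[, j], B = settings$B,
                             alpha = settings$alpha,
                             seed = seed + 1000L * i + j,
                             curtail = settings$curtail)
      c(pt$statistic, as.numeric(pt$significant))
    }),
    cgci = {
      out <- lapply(seq_len(nrow(pairs_dir)), function(r) {
        cg <- cgci(m, pairs_dir$i[r], pairs_dir$j[r], P = P,
                   alpha = settings$alpha)
        c(cg$value, as.numeric(cg$significant))
      })
      tibble::tibble(i = pairs_dir$i, j = pairs_dir$j, type = "causal",
                     value = vapply(out, `[[`, numeric(1), 1),
                     sig = vapply(out, `[[`, numeric(1), 2))
    },
    rcgci = {
      sels <- lapply(seq_len(K), function(t) bts_select(m, t, Lmax = P))
      out <- lapply(seq_len(nrow(pairs_dir)), function(r) {
        rc <- rcgci_from_selection(m, pairs_dir$i[r], pairs_dir$j[r],
                                   sels[[pairs_dir$j[r]]], Lmax = P,
                                   alpha = settings$alpha)
        c(rc$value, as.numeric(rc$significant))
      })
      tibble::tibble(i = pairs_dir$i, j = pairs_dir$j, type = "causal",
                     value = vapply(out, `[[`, numeric(1), 1),
                     sig = vapply(out, `[[`, numeric(1), 2))
    },
    pdc = {
      pd <- pdc(m, P = P, M = settings$n_freq, alpha = settings$alpha)
      s <- pd$summary
      tibble::tibble(i = col_index_lab(pd$labels, s$from),
                     j = col_index_lab(pd$labels, s$to), type = "causal",
                     value = s$frac_sig, sig = s$frac_sig)
    },
    ptenue = {
      out <- NULL
      for (t in seq_len(K)) {
        emb <- build_embedding(m, t, Lmax = settings$Lmax, mode = "lagged",
                               k = settings$k,
                               n_surrogates = settings$B,
                               alpha = settings$alpha_ptenue,
                               seed = seed + 17L * t)
        for (s_ in setdiff(seq_len(K), t)) {
          r <- ptenue_from_embedding(emb, s_)
          out <- rbind(out, data.frame(i = s_, j = t, type = "causal",
                                       value = r$value,
                                       sig = as.numeric(r$significant)))
        }
      }
      tibble::as_tibble(out)
    },
    pmime0 = {
      out <- NULL
      for (t in seq_len(K)) {
        emb <- build_embedding(m, t, Lmax = settings$Lmax, mode = "zero",
                               k = settings$k,
                               n_surrogates = settings$B,
                               alpha = settings$alpha,
                               seed = seed + 17L * t)
        for (s_ in setdiff(seq_len(K), t)) {
          r <- pmime0_from_embedding(emb, s_)
          out <- rbind(out, data.frame(i = s_, j = t, type = r$type,
                                       value = r$value,
                                       sig = as.numeric(r$significant)))
        }
      }
      tibble::as_tibble(out)
    },
    pcmci = {
      g <- pcmci_plus(m, tau_max = settings$tau_max, alpha = settings$alpha,
                      method = "cmi_knn", k = settings$k,
                      k_perm = settings$k_perm, B = settings$B, seed = seed,
                      curtail = settings$curtail, max_conds = settings$max_conds)
      graph_to_cells(g)
    }
  )
}

# flatten a conn_graph into per-cell significance rows; unoriented
# contemporaneous links count in both ordered directions
graph_to_cells <- function(g) {
  K <- g$K
  pairs_dir <- expand.grid(i = seq_len(K), j = seq_len(K))
  pairs_dir <- pairs_dir[pairs_dir$i != pairs_dir$j, ]
  lag_sig <- matrix(0, K, K)
  for (r in seq_len(nrow(g$lagged)))
    if (g$lagged$from[r] != g$lagged$to[r])
      lag_sig[g$lagged$from[r], g$lagged$to[r]] <- 1
  con_sig <- matrix(0, K, K)
  ct <- g$contemporaneous
  for (r in seq_len(nrow(ct))) {
    i <- ct$i[r]; j <- ct$j[r]
    if (ct$orientation[r] == "i->j") con_sig[i, j] <- 1
    else if (ct$orientation[r] == "j->i") con_sig[j, i] <- 1
    else { con_sig[i, j] <- 1; con_sig[j, i] <- 1 }
  }
  rbind(
    tibble::tibble(i = pairs_dir$i, j = pairs_dir$j, type = "contemporaneous",
                   value = con_sig[cbind(pairs_dir$i, pairs_dir$j)],
                   sig = con_sig[cbind(pairs_dir$i, pairs_dir$j)]),
    tibble::tibble(i = pairs_dir$i, j = pairs_dir$j, type = "causal",
                   value = lag_sig[cbind(pairs_dir$i, pairs_dir$j)],
                   sig = lag_sig[cbind(pairs_dir$i, pairs_dir$j)])
  )
}

#' Run the full connectivity benchmark
#'
#' Generates `R` seeded realizations per system (realization `r` uses seed
#' `base_seed + r`, and every measure sees the identical panel), evaluates
#' each measure, and aggregates the per-pair significance indicators into
#' percentage tables. A failing measure on one realization is recorded as
#' missing and the percentage uses the non-missing denominator.
#'
#' @param systems character vector of system ids.
#' @param measures character vector of measure names (see [measure_panel()]).
#' @param R realizations per system.
#' @param n sample size per realization.
#' @param base_seed integer; realization seeds are `base_seed + 1..R`.
#' @param settings a [benchmark_settings()] list.
#' @param cache_dir optional directory: per-(system, measure, realization)
#'   results are cached as RDS files so interrupted runs resume, and a
#'   resumed run reproduces the uninterrupted tables exactly.
#' @param verbose print progress.
#' @return a tibble of class `"conn_benchmark"`: `system`, `measure`, `i`,
#'   `j`, `type`, `pct` (percentage of significant realizations; for PDC the
#'   percentage of significant frequency-realization pairs), `n_used`.
#' @export
run_benchmark <- function(systems = c("S1", "S2", "S3"),
                          measures = c("ppcor", "pspcor", "mi", "cgci"),
                          R = 100, n = 2000, base_seed = 1,
                          settings = benchmark_settings(),
                          cache_dir = NULL, verbose = FALSE) {
  stopifnot(R >= 1)
  rows <- list()
  for (sys in systems) {
    for (r in seq_len(R)) {
      panel <- simulate_system(sys, n = n, seed = base_seed + r)
      for (ms in measures) {
        cell <- NULL
        cache_file <- if (!is.null(cache_dir)) {
          dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
          file.path(cache_dir, sprintf("%s_%s_r%04d.rds", sys, ms, r))
        }
        if (!is.null(cache_file) && file.exists(cache_file)) {
          cell <- readRDS(cache_file)
        } else {
          cell <- tryCatch(
            measure_panel(panel, ms, settings = settings),
            error = function(e) {
              warning(sprintf("measure %s failed on %s realization %d: %s",
                              ms, sys, r, conditionMessage(e)), call. = FALSE)
              NULL
            })
          if (!is.null(cache_file) && !is.null(cell)) saveRDS(cell, cache_file)
        }
        if (!is.null(cell)) {
          cell$system <- sys; cell$measure <- ms; cell$realization <- r
          rows[[length(rows) + 1]] <- cell
        }
        if (verbose) message(sys, " r", r, " ", ms, " done")
      }
    }
  }
  all <- dplyr::bind_rows(rows)
  out <- all |>
    dplyr::group_by(.data$system, .data$measure, .data$i, .data$j, .data$type) |>
    dplyr::summarise(pct = 100 * mean(.data$sig), n_used = dplyr::n(),
                     .groups = "drop")
  class(out) <- c("conn_benchmark", class(out))
  attr(out, "R") <- R
  attr(out, "n") <- n
  attr(out, "base_seed") <- base_seed
  out
}

#' Score a benchmark table against a truth network
#'
#' An edge is *reported* when its percentage is at least `threshold`.
#' Sensitivity is the fraction of truth edges reported; the false-positive
#' rate is the fraction of non-edges reported. Contemporaneous and causal
#' blocks are scored separately (symmetric measures against the unordered
#' contemporaneous pairs, directional ones against the ordered lagged
#' edges).
#'
#' @param table a [run_benchmark()] result (or compatible tibble) for one
#'   system.
#' @param truth a [truth_network()] object.
#' @param threshold reporting threshold in percent, in `(0, 100]`.
#' @return tibble: `measure`, `type`, `sensitivity`, `fpr`, `n_true`,
#'   `n_false`, `spurious` (list-column of reported non-edges).
#' @export
score_benchmark <- function(table, truth, threshold = 50) {
  stopifnot(threshold > 0, threshold <= 100)
  K <- max(table$i, table$j)
  if (nrow(truth$contemporaneous) &&
      max(truth$contemporaneous$i, truth$contemporaneous$j) > K)
    stop("truth network and table have mismatched variable counts", call. = FALSE)
  truth_con <- paste(truth$contemporaneous$i, truth$contemporaneous$j)
  truth_lag <- paste(truth$lagged$from, truth$lagged$to)
  table |>
    dplyr::group_by(.data$measure, .data$type) |>
    dplyr::group_modify(function(d, key) {
      is_con <- key$type == "contemporaneous"
      symmetric <- all(d$i < d$j)
      edge_id <- if (is_con && symmetric) paste(pmin(d$i, d$j), pmax(d$i, d$j))
                 else paste(d$i, d$j)
      truth_ids <- if (is_con) truth_con else truth_lag
      is_true <- edge_id %in% truth_ids
      rep_ <- d$pct >= threshold
      tibble::tibble(
        sensitivity = if (any(is_true)) mean(rep_[is_true]) else NA_real_,
        fpr = if (any(!is_true)) mean(rep_[!is_true]) else NA_real_,
        n_true = sum(is_true), n_false = sum(!is_true),
        spurious = list(edge_id[rep_ & !is_true]))
    }) |>
    dplyr::ungroup()
}

#' Render benchmark tables to files
#'
#' Writes one artifact per system: symmetric measures as upper-triangular
#' blocks, directional measures as full off-diagonal matrices ("rows drive
#' the columns"), and instantaneous measures as side-by-side
#' contemporaneous/causal blocks. Output is byte-stable for identical
#' inputs.
#'
#' @param tables a [run_benchmark()] result.
#' @param dir output directory (created if needed).
#' @param format `"csv"` (tidy long format) or `"text"` (aligned blocks).
#' @return invisibly, the paths written.
#' @export
render_tables <- function(tables, dir, format = c("csv", "text")) {
  format <- match.arg(format)
  if (nrow(tables) == 0) return(invisible(character(0)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sys in sort(unique(tables$system))) {
    d <- tables[tables$system == sys, ]
    path <- file.path(dir, paste0("table_", sys, ".", if (format == "csv") "csv" else "txt"))
    if (format == "csv") {
      ord <- order(d$measure, d$type, d$i, d$j)
      write.csv(as.data.frame(d[ord, c("measure", "type", "i", "j", "pct", "n_used")]),
                path, row.names = FALSE, quote = FALSE)
    } else {
      con <- file(path, "w")
      K <- max(d$i, d$j)
      for (ms in sort(unique(d$measure))) {
        for (tp in sort(unique(d$type[d$measure == ms]), decreasing = TRUE)) {
          dd <- d[d$measure == ms & d$type == tp, ]
          M <- matrix(NA_real_, K, K)
          M[cbind(dd$i, dd$j)] <- dd$pct
          cat(sprintf("%s [%s]\n", ms, tp), file = con)
          hdr <- paste0("     ", paste(sprintf("%6d", seq_len(K)), collapse = ""))
          cat(hdr, "\n", file = con, sep = "")
          for (i in seq_len(K)) {
            cells <- vapply(seq_len(K), function(j) {
              if (i == j) "     -"
              else if (is.na(M[i, j])) "      "
              else sprintf("%6.0f", M[i, j])
            }, character(1))
            cat(sprintf("%4d ", i), paste(cells, collapse = ""), "\n",
                file = con, sep = "")
          }
          cat("\n", file = con)
        }
      }
      close(con)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}
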