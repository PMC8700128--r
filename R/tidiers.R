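#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted VAR
#'
#' One row per (equation, regressor variable, lag) coefficient.
#'
#' @param x a [fit_var()] object.
#' @param ... unused.
#' @return tibble: `equation`, `term_var`, `lag`, `estimate`.
#' @export
tidy.conn_var <- function(x, ...) {
  grid <- expand.grid(equation = seq_len(x$K), r = seq_len(nrow(x$terms)))
  tibble::tibble(
    equation = x$labels[grid$equation],
    term_var = x$labels[x$terms$var[grid$r]],
    lag = x$terms$lag[grid$r],
    estimate = x$A[cbind(grid$equation, x$terms$var[grid$r], x$terms$lag[grid$r])]
  )
}

#' @rdname tidy.conn_var
#' @export
glance.conn_var <- function(x, ...) {
  tibble::tibble(K = x$K, P = x$P, n_eff = x$n_eff,
                 n_params = x$n_params * x$K,
                 sigma2_mean = mean(x$sigma2))
}

#' Tidy a causal-discovery graph
#'
#' @param x a [pcmci_plus()] result.
#' @param ... unused.
#' @return tibble with one row per discovered link: `from`, `to`, `type`
#'   (`"lagged"` with its `tau`, or `"contemporaneous"` with its
#'   orientation), `statistic`, `p_value`.
#' @export
tidy.conn_graph <- function(x, ...) {
  lag <- tibble::tibble(from = x$labels[x$lagged$from], to = x$labels[x$lagged$to],
                        type = "lagged", tau = x$lagged$tau,
                        orientation = NA_character_,
                        statistic = x$lagged$statistic, p_value = x$lagged$p_value)
  con <- tibble::tibble(from = x$labels[x$contemporaneous$i],
                        to = x$labels[x$contemporaneous$j],
                        type = "contemporaneous", tau = 0L,
                        orientation = x$contemporaneous$orientation,
                        statistic = x$contemporaneous$statistic,
                        p_value = x$contemporaneous$p_value)
  dplyr::bind_rows(con, lag)
}

#' @rdname tidy.conn_graph
#' @export
glance.conn_graph <- function(x, ...) {
  tibble::tibble(K = x$K, tau_max = x$tau_max, method = x$method,
                 alpha = x$alpha, n_lagged = nrow(x$lagged),
                 n_contemporaneous = nrow(x$contemporaneous),
                 n_tests = x$n_tests)
}

#' Heatmap of benchmark percentage tables
#'
#' One tile per variable pair, facetted by measure and block type; the tile
#' label is the detection percentage.
#'
#' @param object a [run_benchmark()] result (optionally pre-filtered).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.conn_benchmark <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$j), y = factor(.data$i),
                                  fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$pct)), size = 2.8) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::facet_grid(system ~ measure + type) +
    ggplot2::labs(x = "target / second variable", y = "driver / first variable",
                  fill = "% significant") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Line plot of a simulated panel
#'
#' @param object a [simulate_system()] panel.
#' @param n_points number of leading time points to display.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.conn_panel <- function(object, n_points = 500, ...) {
  d <- tibble::as_tibble(object)[seq_len(min(n_points, nrow(object))), ]
  d$t <- seq_len(nrow(d))
  long <- tidyr::pivot_longer(d, -"t", names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(variable ~ ., scales = "free_y") +
    ggplot2::labs(x = "time", y = NULL,
                  title = paste("system", attr(object, "system") %||% "")) +
    ggplot2::theme_minimal()
}
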