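test_that("benchmark percentages count significance correctly", {
  # single realization: every cell is 0 or 100
  tab <- run_benchmark(systems = "S1", measures = c("ppcor", "cgci"), R = 1,
                       n = 300, base_seed = 10)
  expect_true(all(tab$pct %in% c(0, 100)))
  # symmetric measures store the upper triangle only
  pp <- tab[tab$measure == "ppcor", ]
  expect_true(all(pp$i < pp$j))
  expect_equal(nrow(pp), 10)  # K(K-1)/2 populated cells for K = 5
  # directional measure: full off-diagonal matrix
  cg <- tab[tab$measure == "cgci", ]
  expect_equal(nrow(cg), 20)
  expect_true(all(cg$i != cg$j))
})

test_that("benchmark tables are deterministic and resumable", {
  t1 <- run_benchmark(systems = "S1", measures = "ppcor", R = 3, n = 300,
                      base_seed = 77)
  t2 <- run_benchmark(systems = "S1", measures = "ppcor", R = 3, n = 300,
                      base_seed = 77)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # a cache-backed run, interrupted after one realization, resumes to the
  # identical table
  cache <- file.path(tempdir(), paste0("connbench_cache_", Sys.getpid()))
  unlink(cache, recursive = TRUE)
  run_benchmark(systems = "S1", measures = "ppcor", R = 1, n = 300,
                base_seed = 77, cache_dir = cache)
  t3 <- run_benchmark(systems = "S1", measures = "ppcor", R = 3, n = 300,
                      base_seed = 77, cache_dir = cache)
  expect_identical(as.data.frame(t1), as.data.frame(t3))
  unlink(cache, recursive = TRUE)
})

test_that("a stub measure that always fires yields a table of 100s", {
  panel <- test_panel("S1", n = 300, seed = 3)
  cells <- measure_panel(panel, "ppcor")
  cells$sig <- 1
  # counting oracle: percentage = 100 * mean(sig)
  agg <- stats::aggregate(sig ~ i + j, data = cells, FUN = function(s) 100 * mean(s))
  expect_true(all(agg$sig == 100))
})

test_that("scoring against the truth network separates hits from spurious links", {
  truth <- truth_network("S1")
  # table equal to truth indicator x 100: sensitivity 1, FPR 0
  pairs <- which(upper.tri(matrix(0, 5, 5)), arr.ind = TRUE)
  tab <- tibble::tibble(
    system = "S1", measure = "stub", i = pairs[, 1], j = pairs[, 2],
    type = "contemporaneous",
    pct = ifelse(paste(pairs[, 1], pairs[, 2]) %in%
                   paste(truth$contemporaneous$i, truth$contemporaneous$j),
                 100, 0),
    n_used = 10)
  sc <- score_benchmark(tab, truth, threshold = 50)
  expect_equal(sc$sensitivity, 1)
  expect_equal(sc$fpr, 0)
  # all-zero table: sensitivity 0, FPR 0
  tab0 <- tab; tab0$pct <- 0
  sc0 <- score_benchmark(tab0, truth)
  expect_equal(sc0$sensitivity, 0)
  expect_equal(sc0$fpr, 0)
  expect_error(score_benchmark(tab, truth, threshold = 0))
  # mismatched variable count is caught
  truth_big <- connbench:::new_truth(contemporaneous = rbind(c(1, 7)), lagged = NULL)
  expect_error(score_benchmark(tab, truth_big), "mismatch")
})

test_that("rendered tables have the published layout and are byte-stable", {
  tab <- run_benchmark(systems = "S1", measures = c("ppcor", "cgci"), R = 1,
                       n = 300, base_seed = 10)
  d1 <- file.path(tempdir(), "render1"); d2 <- file.path(tempdir(), "render2")
  p1 <- render_tables(tab, d1, format = "text")
  p2 <- render_tables(tab, d2, format = "text")
  expect_identical(readLines(p1[1]), readLines(p2[1]))
  txt <- readLines(p1[1])
  expect_true(any(grepl("ppcor", txt)))
  expect_true(any(grepl("cgci", txt)))
  pc <- render_tables(tab, d1, format = "csv")
  got <- utils::read.csv(pc[1])
  expect_setequal(unique(got$measure), c("ppcor", "cgci"))
  # empty input: no artifacts
  expect_length(render_tables(tab[0, ], d1), 0)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("tidiers and plots expose the fitted objects", {
  p2 <- test_panel("S2", n = 500, seed = 4)
  fit <- fit_var(p2, P = 2)
  td <- tidy(fit)
  expect_true(all(c("equation", "term_var", "lag", "estimate") %in% names(td)))
  expect_equal(nrow(td), 5 * 5 * 2)
  expect_equal(glance(fit)$P, 2)
  g <- pcmci_plus(p2, tau_max = 2, method = "parcorr", seed = 1)
  expect_true(all(c("from", "to", "type") %in% names(tidy(g))))
  tab <- run_benchmark(systems = "S1", measures = "ppcor", R = 1, n = 300,
                       base_seed = 10)
  pl <- ggplot2::autoplot(tab)
  expect_s3_class(pl, "ggplot")
  pl2 <- ggplot2::autoplot(test_panel("S1", n = 300, seed = 3))
  expect_s3_class(pl2, "ggplot")
})
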