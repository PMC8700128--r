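# connbench

Correlation or causality? When the goal is to infer the connectivity
network of a multivariate system — EEG channels, financial series, gene
activities — the practitioner must choose between symmetric correlation
measures, directional (Granger-style and information-theoretic) causality
measures, and newer *instantaneous causality* methods that estimate
contemporaneous and lagged structure at once. `connbench` turns that choice
into a controlled experiment: it simulates five-variate stochastic systems
whose true contemporaneous and causal wiring is known, runs ten estimators
with their native significance procedures over many seeded realizations,
and tabulates the percentage of realizations in which each (ordered) pair
of variables is declared connected.

## What is implemented

**Simulators** — three systems (`S1`, `S2`, `S3`) with only
contemporaneous, only lagged, and mixed dependence, driven by
non-Gaussian noise (exponential, chi-squared, beta, gamma) used exactly as
defined; seeded, burn-in handled, truth networks exposed as data.

**Correlation measures** (conditioning on all remaining variables):
partial Pearson (`ppcor`) and Spearman (`pspcor`) correlation with the
Student-t test
`t = r * sqrt(n-2) / sqrt(1-r^2)`; partial distance correlation (`pdcor`)
on U-centred distance matrices with a permutation test; and
Kraskov–Stögbauer–Grassberger k-nearest-neighbour mutual information
(`mi_ksg`, k = 10) with a one-sided permutation test (100 shuffles,
add-one rule).

**Causality measures**: the conditional Granger causality index
`CGCI = ln(S_R^2 / S_U^2)` from restricted/unrestricted VAR fits with the
nested F test (`cgci`); its sparse-model variant on BIC-selected lagged
terms (`rcgci`); partial directed coherence
`PDC(f) = |A_ij(f)| / sqrt(sum_k |A_kj(f)|^2)` at 256 frequencies with a
pointwise parametric test (`pdc`); and transfer entropy on a non-uniform
mixed embedding with surrogate-gated term selection (`ptenue`).

**Instantaneous causality**: the mixed-embedding measure with zero-lag
terms (`pmime0`) and constraint-based lagged + contemporaneous discovery
with momentary conditional-independence tests (`pcmci_plus`), with partial
correlation or CMI-kNN local-permutation tests.

**Harness**: `run_benchmark()` sweeps systems × measures × realizations
(shared panels, per-realization caching, resumable), aggregates
percentage-of-significant-links tables, `score_benchmark()` scores them
against the truth networks, `render_tables()` writes the
upper-triangular / full-matrix layouts, and `autoplot()` draws them.

## Worked example

```r
library(connbench)

panel <- simulate_system("S1", n = 2000, seed = 1)   # contemporaneous-only system
ppcor(panel, "X2", "X3")
#> # A tibble: 1 × 7
#>   i     j     measure value statistic   p_value significant
#> 1 X2    X3    ppcor   0.645      37.7 1.58e-235 TRUE
```

The linear `X2–X3` link (true coupling 0.8) gives a partial correlation of
0.645, overwhelmingly significant. The nonlinear `X1–X4` link is invisible
to plain mutual information at this sample size in many realizations —
`mi_ksg(panel$X1, panel$X4)` returns 0.0103 nats here, near the
estimator's independence level, which is why detection percentages rather
than single runs are the package's output:

```r
tab <- run_benchmark(systems = "S1", measures = c("pspcor", "cgci"),
                     R = 10, n = 2000, base_seed = 1)
tab[tab$measure == "pspcor", ]
#>    system measure     i     j type              pct n_used
#>  1 S1     pspcor      1     2 contemporaneous     0     10
#>  3 S1     pspcor      1     4 contemporaneous    50     10
#>  5 S1     pspcor      2     3 contemporaneous   100     10
#>  7 S1     pspcor      2     5 contemporaneous   100     10
#>  9 S1     pspcor      3     5 contemporaneous   100     10
#>  ...

score_benchmark(tab[tab$measure == "pspcor", ], truth_network("S1"))
#>   measure type            sensitivity   fpr n_true n_false spurious
#> 1 pspcor  contemporaneous           1 0.143      3       7 <chr [1]>
```

Rank correlation finds all three true pairs in every realization
(sensitivity 1), the hard nonlinear pair `X1–X4` only half the time at
this replication, and also flags the indirect `X3–X5` association — the
one spurious link (both variables are driven by `X2`). Directional
measures on the same panels stay near the nominal 5% everywhere, since S1
has no causal structure: that contrast is the benchmark's point.

A thin command-line wrapper is included at `inst/cli/connbench.R`
(`simulate`, `measure`, `benchmark` subcommands) for shell pipelines;
panels are interchanged as TSV with a header row of variable labels.

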