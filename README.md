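# panelnet

Symptom-network analysis for two-wave panel studies, built for clinical
research teams who measure a battery of quasi-continuous symptom scores
(questionnaire subscale sums, reaction times) at two time points and want
to know (a) how symptoms hang together within a wave, (b) which symptoms
are central, (c) how trustworthy those answers are, and (d) which
baseline symptoms *predict* other symptoms at follow-up.

The motivating design is a substance-use-disorder cohort: ten nodes —
craving subscales D1–D3, compulsive-drug-seeking subscales O1–O3,
impulsivity subscales B1–B3 and a stop-signal reaction time (SSRT) —
assessed at admission (T0, n = 361) and one month later (T1, n = 209
completers). Because such clinical datasets are typically not deposited,
the package ships a synthetic-data generator with known ground truth so
that every stage of the pipeline is validated by parameter recovery.

## Methods at the core

* **Cross-sectional networks.** Gaussian graphical models: edges are
  partial correlations ρᵢⱼ = −Ωᵢⱼ/√(ΩᵢᵢΩⱼⱼ) from a sparse precision
  matrix Ω estimated by the graphical lasso
  (max_Θ log det Θ − tr(SΘ) − λ‖Θ‖₁,off), with the penalty chosen by the
  extended BIC (EBIC = −2ℓ + E log n + 4γE log p, γ = 0.5) along a
  100-point path, plus a consistency threshold √(log(p(p−1)/2)/n) that
  removes edges indistinguishable from zero. The solver is compiled
  block coordinate descent, verified against an independent
  proximal-gradient oracle.
* **Centrality.** Strength (Σ|w|) and one-step expected influence (Σw),
  raw and z-scored across nodes.
* **Accuracy & stability.** Nonparametric bootstrap (B = 1000) quantile
  intervals per edge, re-running the full estimation each replicate; and
  the case-dropping bootstrap correlation-stability coefficient (CS):
  the largest proportion of cases droppable such that 95% of subsample
  centralities still correlate ≥ 0.7 with the full sample (benchmarks:
  0.25 acceptable, 0.5 good).
* **Cross-lagged panel network.** Directed T0 → T1 network from
  node-wise LASSO regressions on z-standardized completers, penalty by
  seeded 10-fold cross-validation; diagonal = autoregressive effects,
  off-diagonal cross-lagged effects reported above |0.1|; in-/out-
  expected influence per node.
* **Cohort statistics.** Median/IQR + mean/SD descriptives and paired
  T0-vs-T1 comparisons with Shapiro–Wilk branching between the paired t
  test and the Wilcoxon signed-rank test.
* **Redundancy screen.** Dependent-overlapping-correlation z tests
  (goldbricker-style) to catch node pairs that measure the same thing.

## Worked example

```r
library(panelnet)

truth <- default_truth(seed = 2024)   # known 10-node, two-wave ground truth
panel <- simulate_panel(truth)        # 361 subjects at T0, 209 at T1

t0     <- wave_slice(panel, "T0")
net_t0 <- estimate_network(t0)
net_t0
#> <ggm_network> 10 nodes, 7 edges (n = 361, pearson)
#>   lambda = 0.1034, EBIC = 3340.53 (gamma = 0.5)

tidy(net_t0)
#> # A tibble: 7 × 3
#>   node_a node_b weight
#> 1 D1     D2      0.322
#> 2 D1     O2      0.294
#> 3 D3     O3      0.275
#> 4 O1     O3      0.262
#> 5 O1     O2      0.242
#> # …

centrality_table(net_t0) |> dplyr::arrange(dplyr::desc(z_expected_influence))
#> 1 D1       0.615              0.615      1.35                 1.35
#> 2 O3       0.537              0.537      0.967                0.967
#> # …

cs_coefficient(t0, "strength", B_per_drop = 200, seed = 7)
#> <stability_result> index = strength, CS(cor = 0.7) = 0.5 (n = 361, ...)

clpn <- fit_clpn(panel, seed = 7)
clpn
#> <clpn_network> 10 nodes, n = 209 completers, 10-fold CV (min)
#>   9 cross-lagged edge(s) above |0.1|; strongest autoregressive: B3 = 0.449

reported_edges(clpn) |> dplyr::filter(type == "cross_lagged") |> head(3)
#> 1 O1    D1     0.307 cross_lagged
#> 2 D1    O2     0.233 cross_lagged
#> 3 O2    B1    -0.181 cross_lagged
```

Reading the output: the EBIC-selected T0 network keeps 7 edges, with
drug craving and intention (D1) the most central node (highest z-scored
expected influence, 1.35); a strength CS coefficient of 0.5 means node
rankings stay stable (correlation ≥ 0.7 with 95% confidence) even after
dropping half the sample; and the cross-lagged network finds, e.g., that
baseline craving-thought intrusion (O1) positively predicts craving
intention (D1) a month later while drug interference (O2) negatively
predicts attentional impulsivity (B1). At n = 361 the estimated strong
edges (true values 0.30–0.40) and lagged paths are recovered with
shrinkage-typical attenuation.

`run_pipeline(pipeline_config(simulate = list(seed = 1), out_dir = "out"))`
executes all eight stages (descriptives → redundancy screen → per-wave
networks → centrality → bootstrap accuracy → stability → paired
comparisons → CLPN) and writes every table as CSV/JSON plus a manifest;
identical configurations reproduce identical files.

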