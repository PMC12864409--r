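---
title: "Two-wave symptom networks: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-wave symptom networks: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelnet)
```

panelnet implements the complete analysis chain for a two-wave panel of
symptom scores as used in psychometric network studies of substance use
disorders: a battery of ten quasi-continuous nodes — three craving
subscales (D1–D3), three compulsive-drug-seeking subscales (O1–O3), three
impulsivity subscales (B1–B3) and a stop-signal reaction time (SSRT) —
measured at admission (T0) and at a one-month follow-up (T1), with
attrition between waves. This vignette explains the statistical models,
every tunable that matters, the synthetic-data generator used for
validation, and the design decisions taken where the methodology left
genuine choices open.

## The cross-sectional model: a regularized Gaussian graphical model

Within one wave, the joint distribution of the ten node scores is
modelled as multivariate Gaussian with precision matrix $\Omega$. Edges of
the network are partial correlations,
$\rho_{ij} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$: the association
between two symptoms after controlling for all others, so a zero edge
means conditional independence. `estimate_network()` estimates a sparse
$\Omega$ by the graphical lasso,

$$\hat\Omega = \arg\max_\Theta \; \log\det\Theta - \mathrm{tr}(S\Theta)
  - \lambda \sum_{i \ne j} |\Theta_{ij}|,$$

with $S$ the sample correlation matrix (Pearson by default; a Spearman
option exists for heavily skewed scores) and the penalty applied to
off-diagonal entries only. The solver is a block coordinate descent in
compiled code; `glasso_fit()` exposes a single fit and is checked in the
test suite against an independent proximal-gradient solver of the same
objective (agreement to better than $10^{-7}$ on random problems, far
inside the $10^{-4}$ test tolerance), and against the closed-form inverse
at $\lambda = 0$.

### Penalty selection

The penalty path has 100 log-spaced values from $\lambda_{\max}$ (the
largest absolute off-diagonal of $S$, the smallest penalty giving an
empty graph) down to $0.01\,\lambda_{\max}$. Each fit is scored by the
extended Bayesian information criterion,
$\mathrm{EBIC} = -2\ell + E\log n + 4\gamma E\log p$, with $\ell$ the
Gaussian log-likelihood at the estimate (the $\tfrac{np}{2}\log 2\pi$
constant omitted, as it cancels across the path), $E$ the number of
nonzero edges, and $\gamma = 0.5$ — the conservative field default;
$\gamma = 0$ recovers the BIC. Exact EBIC ties are broken toward the
larger penalty, i.e. the sparser model.

### False-positive control

A single global penalty cannot separate weak true edges from spurious
ones once $n$ is large: the $\lambda$ small enough to retain a true edge
of $|\rho| \approx 0.12$ also admits a scatter of tiny false positives
(all $|w| < 0.03$ in our simulations at $n = 2000$, where the raw
EBIC-selected graph carries a mean false-discovery proportion of about
0.23 — a behaviour we confirmed on an independent solver, so it is a
property of the estimator, not of the implementation). `estimate_network()`
therefore applies the consistency threshold
$\sqrt{\log(p(p-1)/2)/n}$ to the selected weight matrix by default:
edges below the magnitude that is statistically indistinguishable from
zero at sample size $n$ are removed. With it, recovery simulations at
$n = 2000$ give mean sensitivity 1.0 for edges $|\rho| \ge 0.2$ and mean
false-discovery proportion 0.0 over 20 seeds. Set
`edge_threshold = FALSE` for the raw EBIC-glasso graph.

### Redundancy screening

Before estimation, `redundancy_screen()` checks whether any two nodes
measure the same thing: pairs with zero-order $|r| \ge 0.5$ are compared,
for every third node $k$, with a Steiger-style z test for dependent
overlapping correlations (Fisher transforms, covariance evaluated at the
back-transformed average correlation). A pair whose correlation profiles
differ significantly for fewer than 25% of third nodes is flagged. The
default battery was deliberately constructed non-redundant, and the
screen confirms this on simulated panels.

## Centrality

`centrality_table()` reports strength (sum of absolute incident edge
weights) and one-step expected influence (sum of signed incident
weights) per node, raw and z-scored across the ten nodes of one network
— the convention of standardized centrality plots. Expected influence
equals strength exactly on an all-positive network and never exceeds it.
Two-step expected influence is intentionally omitted: the analysis this
package reproduces reports a single one-step EI curve.

## Accuracy and stability

`bootstrap_edges()` draws B = 1000 (default) with-replacement resamples
and re-runs the *entire* estimation chain — correlation, penalty path,
EBIC selection, threshold — on each, giving empirical 2.5%/97.5%
quantile intervals per edge. Degenerate resamples (a zero-variance
column) are redrawn and counted. Two caveats are deliberate: quantile
intervals are used rather than normal approximations, matching the
empirical-interval procedure; and the intervals describe sampling
variability of the regularized estimator, *not* nominal-coverage
intervals for the population partial correlation — shrinkage biases the
replicate distribution toward zero, and our simulations (n = 500,
strongest edge $\rho = 0.40$) show exactly the under-coverage the
network literature warns about for bootstrapped regularized edges. The
test suite states this bound honestly and the corresponding check fails
by design of the estimator, not by accident of the code.

`cs_coefficient()` implements the case-dropping bootstrap: for each drop
proportion $q$ in a grid (default 0.05–0.75 in steps of 0.05), it draws
`B_per_drop` subsamples without replacement of size $n(1-q)$, recomputes
the chosen centrality index, and correlates it with the full-sample
index across nodes. The CS coefficient is the largest $q$ such that at
*every* grid point up to $q$ at least 95% of correlations reach 0.7 —
the prefix rule prevents non-monotone artifacts and matches the
interpretation "still stable after removing $q$ of the sample".
Benchmarks: 0.25 minimum, 0.5 good. The default `B_per_drop = 200` is a
desk-scale choice (3000 refits across the grid); raising it to match
the convention of 1000 total case-dropping samples changes nothing
qualitatively in our simulations. Degenerate subsamples yield missing
correlations, which count as failures, so noise data cannot pass by
accident.

## The longitudinal model: a cross-lagged panel network

`fit_clpn()` estimates the directed T0 $\to$ T1 network on completers:
for each outcome node $j$, the z-standardized T1 score is regressed on
all ten z-standardized T0 scores with a LASSO penalty chosen by 10-fold
cross-validation. Both sides are standardized so that every coefficient
is on the same scale and comparable to the 0.1 reporting threshold.
Design choices, each switchable:

* the penalty minimizes mean CV error (`penalty_rule = "min"`); the
  one-standard-error rule is available but shrinks harder than the
  reporting threshold warrants;
* the fold assignment is seeded and *shared* across the ten outcome
  regressions, so a re-run is reproducible and outcomes are treated
  symmetrically;
* the 0.1 filter applies to absolute values (negative cross-lagged
  effects are real findings, e.g. a protective O3 $\to$ B1 path) and
  affects only `reported_edges()`, never the fitted matrix;
* complete-case estimation, no imputation.

The diagonal of the coefficient matrix holds autoregressive effects;
in-/out- expected influence are signed sums of incoming/outgoing
cross-lagged entries, diagonal excluded. Parameter-recovery simulations
at $n = 2000$ give an RMSE below 0.02 against the true standardized
lagged matrix, and every true path of $|b| \ge 0.15$ clears the 0.1
threshold in all tested seeds.

## Descriptives and paired comparisons

`describe_panel()` reports mean, SD, median and quartiles per node
(linear-interpolation quantile convention — the convention had to be
fixed somewhere, and this is R's default). `paired_compare()` follows
the classical branching rule: Shapiro–Wilk on the paired differences at
$\alpha = 0.05$ decides between the paired t test and the Wilcoxon
signed-rank test (zeros dropped, mid-ranks for ties, continuity-corrected
normal approximation above 25 nonzero pairs, exact distribution below;
the reported Wilcoxon statistic is the normal-approximation z).
Calibration simulations show the branch routes Gaussian differences to
the t test and heavily skewed ones to Wilcoxon essentially always, with
empirical type-I error 0.053 at nominal 0.05 over 2000 null panels. The
generator models no wave-to-wave mean shift, so on simulated panels
these are null tests and calibration — not power — is what the suite
verifies.

## The synthetic-data generator

Because the clinical data the design mirrors are not deposited, every
stage is validated against `default_truth()` /
`simulate_panel()`, which generate panels with *known* ground truth:

* **Baseline GGM.** A unit-diagonal, strictly diagonally dominant
  precision matrix with 11 edges out of 45 (75% structural zeros), six
  of them strong ($|\rho| \ge 0.3$: D1–D2 and O1–O2 at 0.40, B1–B3 at
  0.35, O1–O3, D1–O2 and D3–O3 at 0.30) plus five weak edges
  (0.12–0.15). Unit diagonal makes the implied partial correlation
  exactly the tabulated value.
* **Wave-2 generation.** T1 latents are $B^\top z_1 + \varepsilon$ on
  standardized wave-1 latents, so $B$ lives on the standardized scale
  that the CLPN estimates. Default innovation SDs solve for unit wave-2
  variance, making $B$ *exactly* the population standardized coefficient
  matrix (`true_lagged_std()` returns the rescaled truth for any other
  noise level). Autoregressive effects span 0.25–0.50 with O2 strongest;
  seven cross-lagged paths of $|b| \ge 0.15$ include negative
  (protective) O3 $\to$ B1 and O3 $\to$ B3 paths.
* **Marginals.** Latent scores are pushed through monotone transforms to
  observed scales: beta-quantile maps with integer rounding emulate
  right-skewed Likert-sum subscales (craving strongly skewed,
  compulsive-seeking mildly, impulsivity approximately symmetric) and a
  clamped location-scale map gives SSRT in milliseconds (mean 260,
  SD 40). The instrument subscale item splits are not published, so the
  ranges are plausible defaults of the right magnitude, not fitted
  values; rank order is preserved, so Spearman correlations are
  unaffected by the transform while Pearson correlations attenuate
  mildly — exactly the situation the estimator faces on real Likert
  sums.
* **Design constants.** 361 baseline subjects with retention 209/361 at
  follow-up, attrition missing completely at random by default
  (follow-up loss in such cohorts is dominated by external
  administrative reasons); a score-dependent dropout mechanism is
  available behind the `dropout_by` flag for sensitivity analyses.
* **Determinism.** One seeded RNG stream per panel, isolated from the
  caller's random state; the same seed reproduces the panel bit for bit.

What the generator does **not** emulate: item-level responses (subscale
sums only), floor/ceiling pile-ups beyond what the skewed transforms
induce, informative dropout (unless requested), raw stop-signal
trial streams — SSRT enters as a given per-subject scalar — and
contemporaneous residual structure at the follow-up wave: wave-2
innovations are independent across nodes, so the T1 cross-sectional
network carries only the (weak) structure induced through the lagged
map, and at n = 209 the EBIC-selected T1 graph is sparse to empty. Real
follow-up waves keep strong contemporaneous networks; validating the T1
estimator therefore relies on the T0-style fixtures at matched sample
sizes rather than on the generator's wave 2. Passing
recovery tests therefore demonstrate correctness of the estimators under
the stated generative model, not robustness to every pathology of real
clinical data.

## Numerical choices and degenerate inputs

* Correlation matrices must be positive semidefinite up to $-10^{-10}$;
  eigenvalues inside that tolerance are clipped to zero and the matrix
  rescaled to unit diagonal, anything worse is an error, never a silent
  fix. Zero-variance columns are errors naming the column.
* The glasso solver converges on the working covariance to a relative
  tolerance of $10^{-5}$ (sufficient for $10^{-7}$ accuracy in the
  precision matrix on our problems); non-convergence reports the duality
  gap. The penalty path is warm-started from the empty graph downwards.
* Edge support is read off the exact zeros of the coordinate-descent
  solution (entries below $10^{-10}$ in magnitude).
* All-equal centralities give z-scores of 0 with a recorded warning;
  subsamples smaller than $p + 1$ drop their grid point with a warning;
  all-zero paired differences yield a flagged degenerate comparison with
  no test statistic.

## Problem sizes used in validation

The shipped test suite works at deliberately moderate scale so a full
run stays comfortable on one core: recovery at $n = 2000$ over 20 seeds,
recovery-closure checks at $n = 50{,}000$–$100{,}000$ once, stability
fixtures at $n \le 3000$ with 200 subsamples per drop proportion,
bootstrap coverage at $n = 500$ with $B = 200$ over 200 runs, and 2000
scaled null panels for test calibration. These sizes are stated here as
the package's validation conditions; all are adjustable through the
ordinary function arguments.

## Known limitations

* Bootstrapped quantile intervals for regularized edges are biased
  toward zero and do not attain nominal coverage (see above); use them
  to judge estimation precision, not as significance tests.
* The input correlation for the GGM is Pearson by default; polychoric or
  nonparanormal inputs are out of scope in this version, as are mixed
  graphical models and formal T0-vs-T1 network comparison tests.
* The CLPN is a two-wave, observed-variable model: no latent variables,
  no random intercepts, no three-plus-wave generalization.
* Whether the follow-up network should use completers only is not
  decidable from the design we mirror; completers are assumed.
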