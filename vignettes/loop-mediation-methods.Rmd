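---
title: "Causal mediation analysis of closed regulatory loops: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal mediation analysis of closed regulatory loops: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loopmed)
```

# The model

A closed regulatory loop is an ordered triad (miRNA, TF, gene) in which the
miRNA targets both the transcription factor and the gene while the TF targets
the same gene. Expression correlation across samples cannot distinguish the
two causal routes from miRNA to gene, so each loop is analyzed as a
single-mediator structural model with the miRNA as treatment $X$, the TF as
mediator $M$ and the gene as outcome $Y$:

$$
\begin{aligned}
Y &= \beta_1 + cX + e_1,\\
M &= \beta_2 + aX + e_2,\\
Y &= \beta_3 + c'X + bM + e_3.
\end{aligned}
$$

In the linear case the coefficients obey the exact decomposition
$c = ab + c'$, and the quantities of interest are the average causal
mediation effect $\mathrm{ACME} = ab = c - c'$, the average direct effect
$\mathrm{ADE} = c'$ and the total effect $\mathrm{TE} = ab + c'$. These are
causal quantities under *sequential ignorability*: no unobserved confounding
of the $X\to M$, $X\to Y$ and $M\to Y$ relations given the design. For
observational expression data this is a strong assumption, which is why a
sensitivity analysis is part of the core fit (below).

`mediate_loop()` fits all three equations by ordinary least squares and
returns a classed object:

```{r}
set.seed(1)
x <- rnorm(60)
m <- 0.9 * x + rnorm(60, sd = 0.5)
y <- 0.4 * x + 0.8 * m + rnorm(60, sd = 0.5)
fit <- mediate_loop(x, m, y, n_boot = 500, seed = 1)
fit
```

## Uncertainty: bootstrap and Sobel

Inference uses the nonparametric bootstrap: cases are resampled with
replacement, all three equations are refitted, and percentile intervals are
taken at the requested level. Two-sided p-values are
$2\min(\hat F(0), 1-\hat F(0))$, floored at $2/(B+1)$ so that no p-value of
exactly zero is reported from $B$ resamples. For the linear case the
delta-method (Sobel) standard error
$\sqrt{\widehat{se}_a^2 b^2 + \widehat{se}_b^2 a^2}$ is also reported; at
large $n$ it agrees with the bootstrap spread (the test suite requires
agreement within 15% at $n = 1000$).

The linear-path bootstrap is vectorized: for each resample only the five
sufficient moments of $(x, m, y)$ are accumulated and the two $2\times 2$
normal-equation systems solved in closed form, so $B = 1000$ resamples of an
$n = 200$ triad cost tens of milliseconds. Degenerate resamples (zero
variance in a regressor) are redrawn; more than 1% of redraws triggers a
warning.

## Nonlinear edges: cubic regression splines

Edge screening (below) labels each edge *linear* when the Pearson test is
significant. When the treatment–mediator edge is nonlinear the mediator model
uses a cubic regression spline basis (`splines::bs` with three interior knots
at quantiles); likewise for the outcome model when either gene edge is
nonlinear. Effects are then defined by the counterfactual plug-in estimator
evaluated at control/treatment levels $t_0, t_1$ set to the first and third
quartiles of $x$:

$$
\mathrm{ACME} = \frac{\bar{\hat Y}(t_1, \hat M(t_1)) -
                      \bar{\hat Y}(t_1, \hat M(t_0))}{t_1 - t_0},
$$

and analogously for ADE, so spline effects are on the same per-unit scale as
linear coefficients; $\mathrm{TE} = \mathrm{ACME} + \mathrm{ADE}$ holds by
construction. On truly linear data the spline route agrees with the linear
estimates within sampling error (tested).

## Sensitivity to unobserved confounding

For the linear model the ACME as a function of the correlation $\rho$
between $e_2$ and $e_3$ has the closed form

$$
\mathrm{ACME}(\rho) = a\,\frac{\sigma_1}{\sigma_2}
  \left(\tilde\rho - \rho\sqrt{\frac{1-\tilde\rho^2}{1-\rho^2}}\right),
$$

where $\tilde\rho$ is the correlation between the residuals of the
total-effect and mediator equations and $\sigma_1, \sigma_2$ their standard
deviations. `sensitivity()` traces this curve, reports the point estimate at
$\rho = 0$ (which equals $ab$ exactly) and the root $\rho_0$ where the ACME
vanishes — small $|\rho_0|$ means fragile mediation. A planted-confounder
simulation in the test suite checks that $\rho_0$ recovers the constructed
confounding when the true $b$ is zero.

# Edge screening with distance correlation

Regulatory dependence need not be linear. Screening therefore decides edge
significance with the *distance correlation* t-test and uses Pearson only to
route linear vs spline models. Both statistics are implemented from their
definitions (double centering of pairwise distance matrices; the
bias-corrected variant for the t-test with statistic
$T = \sqrt{v-1}\, R^*/\sqrt{1-R^{*2}}$, $v = n(n-3)/2$, on $v - 1$ degrees of
freedom, one-sided upper tail), and each is tested against an independently
coded oracle. A loop is retained when all three of its edges reject
independence at $\alpha = 0.05$; no multiple-testing correction is applied at
this stage by default (a Benjamini–Hochberg option exists), matching the
plain per-edge filter the method prescribes.

Two numerical caveats are documented deliberately:

* the t approximation is reliable from $n \ge 10$; below that the result
  carries a warning;
* the test is *anticonservative* for univariate data at moderate $n$: its
  Student-t null is asymptotic in data dimension, and the measured type-I
  error at $n = 30$, $\alpha = 0.05$ is about 0.070 (30,000 independent-normal
  replicates). The package implements the published test faithfully rather
  than recalibrating it.

# Loop classification

With $\alpha = 0.05$ on bootstrap p-values, a loop is `M_T` when only the
ACME is significant (the TF carries the effect), `M_M` when only the ADE is,
`M_TM` when both are, and `UNEXPLAINED` otherwise. `M_TM` loops are
*supporting* when ACME and ADE share a sign and *opposing* otherwise; using
the signed fold changes of the three members, opposing loops are labeled by
whether the target gene follows the miRNA or the TF. Direction tables count
the characteristic patterns (TF and gene co-directional in `M_T`; miRNA and
gene anti-directional in `M_M`).

# Network motifs

The mediated loops form a directed graph on which the package runs motif
analysis:

* **Canonical ids.** A $k$-node subgraph's id is the minimum over all $k!$
  relabelings of the row-major $k^2$-bit integer of its adjacency matrix
  (e.g. the 4-node single-input module has id 14, the 3-node feed-forward
  pattern id 38). Correctness is established by checking, over *all* 4096
  4-node digraphs, that the id partition coincides with igraph's canonical
  isomorphism partition.
* **Exact census.** Connected induced $k$-subgraphs ($k = 3,4,5$) are
  enumerated exactly once with the ESU algorithm, implemented in C++ for the
  inner loop; counts are validated against a brute-force census over all
  $\binom{n}{k}$ subsets on small graphs.
* **Sampling.** For larger graphs, random root-to-leaf descents of the ESU
  tree with inverse-probability weights estimate motif concentrations.
* **Null model.** Significance is judged against degree-preserving
  edge-switch randomizations (via `igraph::rewire`, three switch attempts
  per edge by default), with the FANMOD-style thresholds $z \ge 2$,
  add-one $p \le 0.05$ and observed count $\ge 5$. Motifs whose null
  distribution is degenerate (zero standard deviation) are reported but
  never called significant.
* **Composition.** Two 4-node motifs can be overlapped on a shared node pair
  (with agreeing internal edges) to form candidate 6-node motifs.

Note that patterns preserved by degree-preserving rewiring (pure stars, for
instance) can never be significant under this null; the planted-motif tests
therefore use bi-fans.

# Synthetic data: what the generator emulates

`generate_dataset()` emulates a two-condition (injured vs sham) expression
study at one time point with planted closed loops. Per triad, coefficients
are drawn from class-consistent ranges ($|a|, |b| \in [0.5, 1.5]$,
$|c'| \in [0.3, 1]$ by default): `M_T` has $c' = 0$, `M_M` has $b = 0$,
`M_TM` all three nonzero, `NULL` all zero. The structural equations generate
the *injured* columns; sham columns are independent noise around a baseline,
and differential expression is planted as a signed baseline ratio (default
4-fold), so the generator exercises the fold-change filter and the
correlation machinery with a single consistent truth table. Decoy
regulator–target edges are added only where they close no unplanted triad,
making inferred loops exactly equal to the truth (precision = recall = 1,
tested). All randomness flows from one integer seed; regeneration is
bit-identical.

One known consequence of the design, kept deliberately: an `M_TM` draw with
$ab \approx -c'$ has a nearly vanishing marginal miRNA–gene dependence
("inconsistent mediation") and can legitimately fail edge screening even
though mediation on the planted triad is significant.

# Pipeline, reproducibility and problem sizes

`run_pipeline()` chains preprocessing, loop inference, screening, mediation,
classification and motif analysis, writing per-stage TSVs, a YAML summary and
a manifest carrying the config, its hash, the seed and the package version.
Reruns with the same config are byte-identical (tested). Per-loop bootstrap
seeds are derived as `seed + i`, so results do not depend on loop order or
parallelism.

Problem sizes used in the validation suite are the package's own choices,
set for statistical power at desk-scale runtimes: e.g. 500 triads of
$n = 200$ with $B = 1000$ for bootstrap bias/coverage (~30 s), 2,000
replicates for test calibration, 100 loops per class for classification
accuracy, graphs of ≤ 12 nodes for exact-census oracles, and 50 seeded runs
of a 100-node planted-bi-fan graph for motif detection.

# Limitations

* Sequential ignorability is untestable from the data; the sensitivity curve
  quantifies, but cannot remove, confounding risk.
* The dcor t-test's anticonservativeness at small univariate $n$ (above).
* Screening on marginal dependence misses canceling (`inconsistent`) `M_TM`
  loops.
* The mediator model is single-mediator per loop; joint multi-TF mediation
  is out of scope.
* Target tables are taken as given; building them from sequence is not
  attempted.
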