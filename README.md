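# loopmed

Causal mediation analysis of closed miRNA → TF → gene regulatory loops.

## The scientific problem

In many disease transcriptomes, a microRNA, a transcription factor (TF) and
a target gene form a *closed regulatory loop*: the miRNA targets both the TF
and the gene, and the TF targets the same gene. Co-expression alone cannot
say whether the miRNA acts on the gene *through* the TF or *directly*.
`loopmed` treats each loop as a single-mediator causal model — the miRNA is
the treatment `X`, the TF the mediator `M`, the gene the outcome `Y`:

```
Y = β1 + cX         + e1        (total effect)
M = β2 + aX         + e2        (mediator model)
Y = β3 + c'X + bM   + e3        (outcome model)
```

so that `c = a·b + c'`, and per loop it estimates

* **ACME** `= a·b = c − c'` — the average causal mediation effect, the part
  of the miRNA's influence carried by the TF;
* **ADE** `= c'` — the average direct effect;
* **TE** `= a·b + c'` — the total effect,

with nonparametric bootstrap confidence intervals and p-values, a Sobel
(delta-method) standard error `sqrt(se_a²·b² + se_b²·a²)` for the linear
case, cubic regression splines when an edge is detectably nonlinear, and a
sensitivity analysis for unobserved mediator–outcome confounding. Loops are
then classified by which effect is significant: `M_T` (TF-mediated), `M_M`
(direct miRNA action), `M_TM` (both), or `UNEXPLAINED`.

Around the core model the package provides the full pipeline: quantile/median
normalization and fold-change + Benjamini–Hochberg differential-expression
filtering, closed-loop inference from regulator–target tables, edge screening
with the distance-correlation t-test (sensitive to nonlinear dependence,
written from the double-centering definitions), and network-motif analysis of
the mediated-loop graph (exact ESU subgraph enumeration in C++, canonical
motif ids, degree-preserving randomization nulls). A seeded synthetic-data
generator plants loops of each class so every stage can be validated against
known truth.

## Worked example

Generate a small dataset with planted loops, infer and screen the candidate
loops, and fit the mediation model to one of them:

```r
library(loopmed)

ds <- generate_dataset(n_triads = c(M_T = 2, M_M = 2, M_TM = 2, `NULL` = 2),
                       n_samples = 40, n_decoy_edges = 20, seed = 7)
loops    <- infer_closed_loops(ds$mirna_targets, ds$tf_targets)  # 8 loops
screened <- screen_loops(loops, ds$mirna_expr, ds$tf_expr, ds$gene_expr)
nrow(screened)   # 6 — the 2 NULL loops fail the dependence screen

inj <- ds$mirna_expr$meta$condition == "injured"
fit <- mediate_loop(x = ds$mirna_expr$values["miR_005", inj],
                    m = ds$tf_expr$values["TF_005", inj],
                    y = ds$gene_expr$values["G_005", inj],
                    n_boot = 1000, seed = 1,
                    loop = c("miR_005", "TF_005", "G_005"))
summary(fit)
```

```
Causal mediation analysis of loop miR_005 -> TF_005 -> G_005
orientation: miRNA_treats_TF_mediates  models: linear / linear  n = 40
             Estimate 95.0% CI lo   CI hi p-value
ACME          -1.7221     -2.2429 -1.2375   0.002
ADE            0.9363      0.4558  1.3210   0.002
Total effect  -0.7858     -1.1216 -0.4451   0.002

path coefficients: a = -1.111  b = 1.55  c' = 0.9363  c = -0.7858
Sobel SE of ACME: 0.2566  normal CI: [ -2.225, -1.219 ]
bootstrap: 1000 resamples, seed 1
```

The planted coefficients were `a = -1.06`, `b = 1.49`, `c' = 0.75`; the fit
recovers them within sampling error, and the decomposition
`TE = ACME + ADE` (`-0.7858 = -1.7221 + 0.9363`) holds exactly. Both effects
are significant and of opposite sign, so the loop classifies as an
*opposing* `M_TM` loop whose target gene follows the miRNA:

```r
cl <- classify(fit, fc = c(mirna = 4, tf = -4, gene = 4))
subclassify_mtm(cl)[, c("cls", "agreement", "tg_follows")]
#>    cls agreement tg_follows
#> 1 M_TM  opposing      miRNA
```

How much hidden mediator–outcome confounding would explain the ACME away?

```r
sensitivity(fit)
#> ACME sensitivity to mediator-outcome error correlation rho
#> ACME at rho = 0: -1.722
#> rho where ACME = 0: 0.7889
```

The whole pipeline (differential expression → loops → screening → mediation →
classification → motifs) runs from one config:

```r
cfg <- validate_config(list(
  synthetic = list(n_triads = list(M_T = 3, M_TM = 3, `NULL` = 2),
                   n_samples = 60),
  n_boot = 500, n_random_graphs = 200, motif_sizes = c(3, 4), seed = 11))
res <- run_pipeline(cfg, "results/run1")
```

which writes per-stage TSVs, a YAML summary of class/direction counts and a
reproducibility manifest. In the mediated-loop graph the closed regulatory
triad itself (motif id 38, the feed-forward pattern) shows up as the
significant 3-node motif against degree-preserving random graphs.

## Package layout

* `R/synthetic-data.R` — seeded generator with planted loop classes and fold
  changes; `R/expression-matrix.R` — the `expr_matrix` container and TSV IO.
* `R/preprocess.R` — normalization, differential expression, time-point
  imputation, probe collapsing.
* `R/loop-inference.R` — target-table de-duplication, closed-loop triple
  join, loop graph construction.
* `R/edge-screening.R` — Pearson edge test, distance correlation (plain and
  bias-corrected), the dcor t-test, loop screening.
* `R/mediation.R` — `mediate_loop()` and the `loop_mediation` S3 class with
  `print`, `summary`, `coef`, `confint`, `plot`, `residuals` and
  `sensitivity` methods.
* `R/loop-classification.R` — class assignment, M_TM sub-classification,
  direction tables, top effects.
* `R/motif-analysis.R` + `src/motifs.cpp` — canonical motif ids, exact and
  sampled ESU enumeration, degree-preserving nulls, motif composition.
* `R/pipeline.R` — config validation and the end-to-end runner.

See `vignettes/loop-mediation-methods.Rmd` for the model, assumptions and
numerical choices.
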