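# ppistrength

Predicting the *strength* of protein–protein interactions (PPIs) from
protein domain information.

Interactome screens attach weights to protein pairs — repeated
detections, reliability scores — which, normalised by the largest
weight, become real-valued interaction strengths ρᵢⱼ ∈ [0, 1]. This
package predicts such strengths for new pairs using only the domain
composition and domain sequences of the two proteins. It is aimed at
computational biologists benchmarking domain-based strength predictors
or building features for interactome modelling.

## What is inside

Everything rests on the noisy-OR model: two proteins interact iff at
least one pair of their domains does, so

    Pr(P_ij = 1) = 1 − ∏_{Dm ∈ Pi, Dn ∈ Pj} (1 − Pr(D_mn = 1)).

* **Domain-pair estimators** `assocScores()` (binary data),
  `asnmScores()` (mean strength over supporting pairs) and
  `apmScores()` (exponent-corrected: each supporting pair contributes
  `1 − (1 − ρ)^(1/(|Pi||Pj|))`), with `predictStrength()` as the
  noisy-OR combiner and `coverageFilter()` restricting test pairs to
  those fully scored by a training split.
* **Feature mappings** for kernel regression: `dnFeatures()` (domain
  multiplicities, dimension 2T), `spdFeatures()` (k-mer spectra of the
  domain-restricted sequence over a 21-letter alphabet, dimension
  2·21^k) and `apmFeatures()` (the scalar combined APM score).
* **Regressors** with the Laplacian kernel K(x,y) = exp(−σ‖x−y‖):
  `svrFit()` (ε-insensitive SVR solved in the dual by an established
  convex backend) and `rvmFit()` (a from-scratch relevance vector
  machine fitted by evidence maximisation).
* **Evaluation**: `runProtocol()` — threefold outer cross-validation
  with nested fivefold selection of σ, per-fold coverage filtering,
  RMSE reporting and a full per-pair prediction dump.
* **Synthetic benchmarks**: `generateDataset()` plants a known
  domain–domain interaction probability matrix and emits FASTA +
  annotation TSV + weighted-pair TSV; `paperShapeConfig()` mirrors the
  shape of the classic yeast benchmark (758 proteins, 327 domains,
  1387 + 100 pairs).

The methods vignette (`vignettes/predicting-ppi-strength.Rmd`) derives
each component and records every design and numerical decision.

## A worked example

```r
library(ppistrength)

cfg <- generatorConfig(n_proteins = 40, n_domains = 12, n_pairs = 80,
                       zero_pair_count = 10, seed = 7)
dataset <- generateDataset(cfg)$dataset
dataset
#> PairDataset: 90 pairs over 40 proteins (T = 12 domains)
#>   strengths: 10 zero, mean 0.4958, max 1.0000

apm <- apmScores(dataset)
head(scoreTable(apm), 3)
#>   domain_a domain_b       score support
#> 1    D0001    D0001 0.040465471       1
#> 2    D0001    D0002 0.039196456       7
#> 3    D0001    D0003 0.007426072       4

report <- runProtocol(dataset, mapping = "dn", modelKind = "svr",
                      seed = 42, CGrid = 1)
report
#> EvaluationReport: svr + dn
#>  C meanTrainRMSE meanTestRMSE
#>  1     0.1266629    0.2619943

reportResults(report)[, c("fold", "sigma", "trainRMSE", "testRMSE",
                          "nKept", "nDropped", "nVectors")]
#>   fold sigma trainRMSE  testRMSE nKept nDropped nVectors
#> 1    1   0.1 0.1114262 0.2906442    20       10       46
#> 2    2   0.1 0.1306813 0.2669677    26        4       45
#> 3    3   0.1 0.1378811 0.2283710    29        1       50
```

Reading the output: 90 pairs (80 weighted + 10 added zero-strength)
over 40 proteins; the APM table assigns each supported domain pair a
probability and its supporting-pair count. The protocol report gives,
per outer fold, the inner-CV-selected bandwidth σ, training RMSE on
the outer-training pairs, test RMSE on the pairs kept by the coverage
filter (`nKept`/`nDropped`), and the support-vector count; the summary
row averages the three folds. With `modelKind = "rvm"` the same report
carries relevance-vector counts, and `modelKind = "apm_baseline"`
evaluates the noisy-OR combiner directly with no regression.

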