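---
title: "Predicting protein-protein interaction strength from domain features"
author: "ppistrength"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interaction strength from domain features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppistrength)
```

# The problem

Large-scale interactome screens report not only *whether* two proteins
interact but, indirectly, *how strongly*: repeated detections across
experiments, or reliability weights attached to interactome edges, can
be read as an interaction strength $\rho_{ij} \in [0,1]$ once
normalised by the largest weight in the collection. This package
predicts such strengths for new protein pairs from protein **domain**
information alone: which conserved domains each protein carries, where
those domains sit in the sequence, and what the domain subsequences
look like.

Two families of predictors are provided:

1. **Association-style estimators** that infer a probability of
   interaction for every *domain pair* from the training pairs and then
   recombine those probabilities into a pair strength.
2. **Kernel regressors** (epsilon-insensitive SVR and a relevance
   vector machine) over explicit feature vectors built from the domain
   annotations.

Both are evaluated by the same cross-validated protocol with RMSE as
the loss.

# The generative model

The domain-based view assumes two proteins interact iff at least one
pair of their domains interacts. If $D_{mn} = 1$ denotes the event that
domains $D_m$ and $D_n$ interact, independence across domain pairs
gives

$$\Pr(P_{ij}=1) \;=\; 1-\prod_{D_m\in P_i,\,D_n\in P_j}
  \bigl(1-\Pr(D_{mn}=1)\bigr),$$

a noisy-OR over all domain *instance* pairs. Throughout the package a
domain occurring twice in a protein contributes two factors to this
product (`predictStrength()`); this multiplicity-aware reading is
consistent with the domain-count feature below, which also counts
instances. The protein pair is treated as unordered everywhere.

## Estimating domain-pair probabilities

Given training pairs $\mathcal{P}$ with strengths $\rho_{ij}$, a pair
$(P_i,P_j)$ *supports* the domain pair $(D_m,D_n)$ when $D_m$ occurs on
one protein and $D_n$ on the other, in either orientation, counted once
per protein pair. Three estimators share this support definition and
differ only in what they average:

* **ASSOC** (binary data): the fraction of supporting pairs that
  interact.
* **ASNM** (real-valued data): the mean strength over supporting
  pairs. On 0/1 strengths it reduces exactly to ASSOC, which the test
  suite checks on randomised datasets.
* **APM**: before averaging, each supporting pair's strength is
  converted into a per-domain-pair probability under the assumption
  that all of its $|P_i||P_j|$ domain pairs contribute equally:
  $1-(1-\rho_{ij})^{1/(|P_i||P_j|)}$. Because the exponent is
  $\le 1$, APM scores never exceed ASNM scores.

$|P_i|$ counts domain *instances* by default. The choice is genuinely
open — "the set of domains of a protein" can be read as a set or a
multiset — so `apmScores(distinctDomains = TRUE)` switches to distinct
ids; the default keeps the multiset reading to stay consistent with the
multiplicity-aware noisy-OR product and domain-count features.

Domain pairs without any supporting protein pair are *absent* from the
score table, not zero: absence means "no evidence". That distinction
drives the **coverage filter**: at test time a pair is scored only if
*every* one of its domain pairs received a training score, since a
single missing factor makes the noisy-OR product undefined rather than
small. Pairs involving a protein without any annotated domain have no
enumerable domain pair; they are dropped by the filter rather than
vacuously kept, because no domain evidence can speak for them.

# Feature mappings

For the regressors, each (canonically ordered) protein pair is mapped
to a numeric vector:

* **DN** — domain counts. With a domain universe of size $T$ (the
  sorted distinct domain ids of the dataset), entries $1..T$ hold the
  multiplicities of each universe domain in the first protein, entries
  $T+1..2T$ those of the second: dimension $2T$.
* **SPD** — domain-restricted spectrum. Each protein's domain
  subsequences are concatenated in order of appearance and the
  $k$-mer counts of the concatenation are taken over a 21-letter
  alphabet (20 standard residues plus one catch-all for B, Z, J, X, U,
  O and anything else). The pair vector concatenates both proteins'
  spectra: dimension $2\cdot 21^k$. Unlike DN, two pairs with identical
  domain composition but different sequences get different SPD vectors.
* **APM score** — the scalar noisy-OR combination of training APM
  scores, dimension 1.

Two SPD conventions deserve note, since either choice silently changes
results. $k$-mers spanning the junction between two concatenated domain
subsequences **are** counted (the spectrum is taken over the
concatenated string, which is how the restriction is defined), and
overlapping domain regions are extracted independently, so shared
residues appear once per instance. Swapping the two proteins of a pair
never changes a feature vector: pairs are sorted lexicographically by
protein id before mapping.

# The regressors

Both regressors use the Laplacian kernel
$K(x,y)=\exp(-\sigma\lVert x-y\rVert)$ with the Euclidean norm.

## Support vector regression

The epsilon-insensitive primal
$$\min \tfrac12\lVert w\rVert^2 + C\sum_i(\xi_i+\xi_i')$$
is solved through its standard dual in
$\beta_i = \alpha_i-\alpha_i'$:
$$\max\; y^\top\beta - \epsilon\lVert\beta\rVert_1
  - \tfrac12\beta^\top K\beta
  \quad\text{s.t.}\quad \textstyle\sum_i\beta_i=0,\; |\beta_i|\le C.$$
The QP is handed to an established convex backend: an interior-point
solver on the explicit dual for up to 100 training points (where its
answers are essentially exact — the test suite compares the attained
dual objective against an independent active-set enumeration of a
5-point problem to 1e-6), and SMO above that (the two backends agree to
~1e-4 on mid-size problems, also under test). The intercept is
recovered from the KKT conditions: exactly at interior coefficients,
as the feasible-interval midpoint when every coefficient sits at a
bound. $\epsilon$ defaults to 0.1, the long-standing default of kernel
SVR implementations in R; support vectors are coefficients with
$|\beta_i| > 10^{-8}$.

## Relevance vector machine

The RVM is Bayesian linear regression over the data-dependent basis
$\Phi = [\,1, K(\cdot,x_1),\dots,K(\cdot,x_N)\,]$ ($M=N+1$ weights)
with noise precision $\beta$ — i.e.
$p(y\mid x, w, \beta) = \mathcal{N}(y \mid w^\top\phi(x), \beta^{-1})$
— and an individual prior precision $\alpha_i$ per weight,
$p(w\mid\alpha)=\prod_i \mathcal{N}(w_i\mid 0, \alpha_i^{-1})$. (Some
write-ups call $\sigma^2$ itself the noise parameter; this package
follows the standard convention that $\beta$ is the *precision*, so
the model variance is $1/\beta$.) Evidence maximisation iterates

$$\Sigma = (\beta\Phi^\top\Phi + \mathrm{diag}\,\alpha)^{-1},\quad
  \mu = \beta\,\Sigma\,\Phi^\top y,$$
$$\gamma_i = 1-\alpha_i\Sigma_{ii},\quad
  \alpha_i \leftarrow \gamma_i/\mu_i^2,\quad
  \beta \leftarrow \frac{N-\sum_i\gamma_i}{\lVert y-\Phi\mu\rVert^2},$$

pruning bases whose $\alpha_i$ exceeds $10^{12}$ and stopping when
$\max_i|\Delta\log\alpha_i| < 10^{-6}$ (at most 1000 sweeps). The
retained kernel bases are the relevance vectors. Initial values are
$\alpha_i = 10^{-4}$ and $\beta = 100/\mathrm{var}(y)$.

One scheduling choice matters and is easy to get wrong: with a
still-flat prior the full $N{+}1$ basis interpolates $y$ on the very
first sweep, the residual collapses to $\sim 10^{-10}$, and an
immediately re-estimated $\beta$ diverges before any $\alpha_i$ can
prune its basis — the model then never leaves interpolation. The
package therefore holds $\beta$ at its initial value for the first 10
sweeps and caps its growth at 4x per sweep afterwards. With this
schedule the log evidence is non-decreasing across sweeps (checked to
1e-8 per step) and a 50-point fixture generated from 3 kernel bumps
plus 1% noise is recovered with exactly 3 relevance vectors.

Predictions from both models are raw regression outputs; clipping to
$[0,1]$ is available (`predict(..., clip = TRUE)`) but off by default,
since RMSEs on raw outputs are the conventional report.

# The evaluation protocol

`runProtocol()` runs threefold outer cross-validation:

* Pairs are put in canonical key order first, so reports depend only on
  the pair set and the `CVPlan`, never on input order. Folds are
  seeded, balanced to within one pair, and recorded in the report.
* Per outer fold, the APM table is estimated from the **training pairs
  only**, and test pairs failing the coverage filter against that table
  are dropped — for every model, so all models are scored on the same
  kept pairs. (For the feature models an unfiltered test RMSE is also
  reported, clearly separated.) A sentinel test perturbs the test-fold
  strengths and verifies the fitted models do not change.
* The kernel bandwidth $\sigma$ is selected per fold by fivefold inner
  cross-validation over a grid, minimising mean validation RMSE; exact
  ties go to the smallest $\sigma$; candidates whose training fails
  (the RVM on the scalar APM feature cannot be trained at small
  bandwidths) are skipped with a recorded reason. Default grids follow
  the protocol conventions: $\sigma \in \{0.01, 0.02, \dots, 0.1\}$,
  switched automatically to $\{3.0, 3.1, \dots, 9.0\}$ for RVM on the
  APM-score feature, and $C \in \{1, 2, 5\}$ for SVR. The RVM has no
  $C$, so it is fitted once per fold. Within the inner loop the
  APM-score feature reuses the outer-training table; outer-level
  train/test separation is what the leakage guarantee covers.
* Training RMSE is computed on the full outer-training set (not
  averaged over inner folds), test RMSE on the kept test pairs, and the
  reported averages are arithmetic means over the 3 folds. The report
  retains the full per-pair prediction dump, from which every RMSE can
  be recomputed.
* Zero-strength pairs are added once, before cross-validation, not
  re-sampled per fold.

# The synthetic benchmark generator

`generateDataset()` produces the three interface files' worth of data
(sequences, annotations, weighted pairs) with *planted* structure, so
every claim above is testable without external databases:

* a domain universe in which every domain is guaranteed at least one
  instance (universe coverage is dealt round-robin before random
  assignment);
* proteins of 1-4 domain instances, with a 10% chance per slot of
  repeating an already-chosen domain, exercising multiplicity;
* one conserved prototype sequence per domain, copied into each
  instance with 5% point substitutions, so SPD sees conserved but
  non-identical domain sequences; linkers and a 2% ambiguity-code rate
  exercise the 21st alphabet symbol;
* a sparse planted DDI probability matrix (density 0.05, probabilities
  uniform on [0.1, 0.9]); clean strengths follow the noisy-OR model
  exactly (re-verified to 1e-12 in tests); emitted strengths are
  clean values plus truncated Gaussian noise (default sd 0.02);
  interacting pairs are preferred when sampling the weighted pair
  list, mimicking an interactome edge list, and zero-strength absent
  pairs are appended;
* `paperShapeConfig()` reproduces the *shape* of the reference
  benchmark (758 proteins, 327 domains, 1387 + 100 pairs) for scale
  and dimension checks (DN dimension 654, SPD $k{=}1$ dimension 42).

What the generator does **not** emulate: real interactome weight
distributions (its strengths are noisy-OR values, not reliability
scores), homologous domains with correlated but distinct ids,
disordered regions, or annotation errors. Passing the recovery tests
therefore shows internal consistency of the pipeline — on data
generated by the model class the estimators recover the planted truth
— not predictive performance on real interactomes.

On noise-free data where every protein has exactly one domain, ASNM
and APM tables equal the planted probability matrix exactly and the
APM baseline attains zero test RMSE on covered pairs; this parameter
recovery is part of the acceptance suite.

# Numerical choices

* The noisy-OR product accumulates $\sum\log(1-s)$ via `log1p`, so
  factors arbitrarily close to 0 or 1 neither underflow nor lose
  relative precision (contract: 1e-9 against a naive-product oracle,
  tested).
* Coordinates are 1-based inclusive end to end — the native convention
  of R and of UniProt-style feature tables — rather than converted to
  half-open internally.
* The interior-point SVR path adds a 1e-10 ridge to the (rank-deficient)
  dual Hessian; duplicated training rows fall back to SMO.
* The RVM adds 1e-10 jitter to the posterior precision only if the
  Cholesky factorisation fails, with a warning.
* Score tables and pair strengths serialise at 17 significant digits,
  so the three-file round trip is bit-exact.

# Problem sizes used by the checks

The test suite runs the full protocol once at the benchmark shape
(1487 pairs, SVR + DN, one C, full bandwidth grid) and keeps all other
fixtures at 10-60 proteins, sizes at which every brute-force oracle is
exact and fast. `scripts/acceptance.R` evaluates all seven
model/feature combinations on a 290-pair benchmark (120 proteins, 40
domains) with the full default grids; these sizes are the package's
own reporting choice for a complete, reproducible sweep.

# Known limitations

* APM training assumes every supporting protein has at least one
  domain instance (the exponent $1/(|P_i||P_j|)$ is undefined
  otherwise); domain-free proteins never support a domain pair, and
  their pairs are dropped by the coverage filter.
* The SVR/RVM feature models can be evaluated on uncovered test pairs
  (unfiltered RMSE) but the APM baseline cannot; comparisons should
  use the filtered numbers, which are computed on identical pair sets.
* The RVM evidence ascent is a fixed-point iteration, not a guaranteed
  ascent method; monotonicity is verified empirically to 1e-8 per
  sweep on the tested problem classes, not proven.
* `readFasta()`/`readDomainAnnotations()` expect the package's plain
  interface formats; converting real UniProt flat files or interactome
  releases is out of scope.
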