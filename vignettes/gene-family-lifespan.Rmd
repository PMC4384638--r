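---
title: "Gene-family size and lifespan on a phylogeny: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family size and lifespan on a phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylofam)
```

## The question and the model

Does the number of genes in a family — here the CD33-related Siglecs, with
kallikreins (KLK), Toll-like receptors (TLR) and IgG Fc receptors as
negative controls — covary with maximum lifespan across mammals? Species are
not independent data points: covariance induced by shared ancestry must be
modelled before a cross-species slope can be tested.

phylofam assumes traits evolve by Brownian motion (BM) on a rooted,
branch-length-bearing tree. Under BM the trait covariance of two species is
proportional to the shared branch length from the root to their most recent
common ancestor; `phylo_vcv()` builds that matrix V. Pagel's lambda scales
the off-diagonal of V, interpolating between full phylogenetic structure
(lambda = 1) and species independence (lambda = 0); it is the package's only
covariance transform (kappa, delta and Ornstein-Uhlenbeck structures are out
of scope).

Two estimators share this model and, for a single predictor, a slope:

* **PGLS** (`pgls_fit()`): GLS with covariance `V_lambda`, an intercept, and
  per-coefficient t tests. Lambda may be fixed or ML-estimated.
* **Independent contrasts** (`felsenstein_contrasts()` +
  `fic_regression()`): the pruning recursion standardizes sister-lineage
  differences; regression is through the origin after orienting each pair so
  the x contrast is non-negative (ties keep their orientation; the slope and
  SE are invariant to this cosmetic step).

The suite enforces the classical identity — contrasts slope equals the
PGLS(lambda = 1) slope — to 1e-8 on simulated data, and checks PGLS against
an explicit-inverse GLS oracle, `ape::pic`, `nlme::gls` and
`phytools::phylosig`.

## Parameters that matter

* **lambda** (unitless, [0, 1]; default 1 in the base grid). The
  reproduction grid fixes lambda = 1 — the classical full-BM analysis; the
  body-mass-controlled refit estimates lambda by ML, mirroring the two-stage
  design of the study this pipeline reproduces. The original tools' internal
  lambda handling for the first stage is not documented, so the package
  makes the choice explicit and lets the user refit with `lambda = "ml"`.
* **Degrees of freedom.** The reproduced study fixed df = 11 at n = 14 for
  both PGLS and contrasts (n - 3: one for computing contrasts, two for slope
  and intercept). Standard practice is n - 2 (contrasts: n_contrasts - 1).
  Both are implemented (`df_convention = "paper"` / `"standard"`); "paper"
  is the default only in the reproduction entry points, and the same df is
  used for the residual-variance estimate, since the source tools' internals
  are unstated. Sensitivity refits apply the chosen rule to the reduced n
  (13 taxa -> df 10).
* **Log transform** (base 10 by default). Lifespan (years) and body weight
  (grams) are log-transformed; gene counts are not. The base is cosmetic:
  r², t and p are invariant to it (tested).
* **Response orientation.** The single-predictor grid regresses log lifespan
  on gene count; the mass-controlled model takes gene count as the response
  with log lifespan and log body weight as covariates. Simple-regression t
  is symmetric in x and y, so only the reported slope depends on the first
  choice.
* **Epsilon policy.** Contrast expected variances are floored at 1e-12, so
  zero-length branches (including those created by polytomy resolution)
  never divide by zero.

## Numerical choices

* **Lambda profiling.** `V_lambda = lambda V + (1 - lambda) diag(V)` is
  diagonalized once via the eigendecomposition of `D^(-1/2) V D^(-1/2)`
  (D = diag(V)); each likelihood evaluation is then a weighted least-squares
  solve, making 1,000 ML fits on a 200-leaf tree cheap. A 41-point grid
  brackets the optimum; golden-section search refines to 1e-6; estimates
  within 1e-6 of a boundary are reported exactly as 0 or 1. ML is the
  default criterion (REML available via `reml = TRUE` but unused in
  reproduction mode). A flat profile (range < 1e-9, e.g. a star tree)
  returns `lambda_hat = NA` with a flag rather than an arbitrary value.
* **Fixed-lambda fits** whiten through a Cholesky factor; the brute-force
  explicit-inverse oracle in the tests guards the shortcut.
* **Polytomies** are resolved into a ladder of zero-length branches,
  combining children in order of smallest leaf label — deterministic, and
  provably covariance-neutral (tested).
* **Pruning and the root edge.** `prune_to_taxa()` re-roots at the MRCA of
  the retained set and discards any path above it, so depths are measured
  from the new root. The pruned covariance therefore equals the
  corresponding submatrix of the full covariance minus a constant (the new
  root's former depth); under lambda = 1 with an intercept, regression
  results are invariant to that constant. The tests check the shifted
  identity exactly.
* **Newick I/O.** The parser reports 1-based character positions for
  errors, accepts quoted labels and bracket comments, and the writer emits
  the shortest decimal that round-trips each branch length, so
  parse-write-parse is the identity.
* **t tail areas** use the regularized incomplete beta function and are
  checked against quadrature at 1e-10 and the Cauchy closed form at df = 1.

## The synthetic-data generator

`simulate_yule_tree()` draws pure-birth trees (exponential epochs of rate
`k * birth_rate`; expected depth `sum_{k=2..n} 1/(k b)`, verified by Monte
Carlo). `simulate_bm_traits()` draws leaf values directly from the
matrix-normal distribution with covariance `V_lambda (x) R` (R the
evolutionary rate matrix), using a Cholesky root of `V_lambda` and a
symmetric square root of R. Simulating from the transformed covariance —
rather than branch-wise — honors lambda exactly, which branch-wise
simulation cannot do for lambda < 1. Gene-count-like traits are rounded and
floored at zero after simulation; the tests confirm this perturbs r² by
under 0.05 on average at fixture scale, supporting the Gaussian treatment of
integer counts.

Validation sizes, chosen to give tight Monte-Carlo error at interactive
runtimes: slope identity on 100 datasets of 5-20 taxa; lambda recovery with
500 replicates on a 200-leaf tree at true lambda 1 and 0 (mean estimates
recovered within 0.05 and 0.1); type-I error of FIC and PGLS(lambda = 1)
within [0.03, 0.07] at nominal 0.05 over 2,000 null replicates at n = 14,
where naive Pearson on the same data rejects at about four times the nominal
rate on imbalanced trees — the quantitative case for phylogenetic
correction.

What the generator does *not* emulate: gene birth-death dynamics (counts are
rounded Gaussians, not a duplication-loss process), measurement error in
life-history databases, tree uncertainty, and non-BM trait evolution.
Passing recovery tests show the estimators are correct under their own
model, not that mammal gene counts follow it.

## The packaged fixture is a stand-in

The original study's species table and the two chronograms are published
only as figure panels, so they cannot be carried as data. The packaged
fixture (`*_synthetic.*` under `extdata/`) was assembled once from public
sources: the 14 species named in the study, their AnAge maximum lifespans
and adult body weights, gene counts informed by the comparative Siglec/KLK/
TLR/FcR literature (e.g. ten functional CD33rSiglecs in humans, five in
mouse, an expanded rodent KLK cluster, a human-specific excess of Fc
receptor genes), and two chronograms with divergence times in the range of
published mammal supertrees. The three later-sequenced primates ship with
their reported Siglec counts (5, 5, 4) and no lifespans, which must come
from AnAge.

On this stand-in the qualitative structure of the study emerges without any
tuning: the Siglec family shows much the strongest raw correlation with log
lifespan; the lifespan effect survives the body-mass-plus-phylogeny
correction (t ≈ 3.3) while the syntenic KLK control does not; the Fc
receptor contrast signal is driven by the human outlier and collapses when
humans are excluded. One feature does **not** reproduce: the stand-in's
counts vary smoothly along the tree, so the single-predictor PGLS/FIC p
values at lambda = 1 are not significant — the within-clade count variation
that drove the original contrasts is exactly the information a transcribed
figure would carry and a literature-level reconstruction does not. The
pipeline's numerical claims are therefore validated by simulation and by
dual-route recomputation on the fixture, never by comparison to the study's
printed statistics.

## Known limitations

* Gene counts are modelled as continuous Gaussians; no phylogenetic Poisson
  or logistic alternative is offered.
* lambda > 1 and other branch-length transforms are rejected by design.
* Trees must be rooted with branch lengths; there is no inference, dating or
  rerooting machinery.
* The human-exclusion refit's df convention in the original analysis is
  unstated; the package applies its chosen rule (n' - 3) and documents it.
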