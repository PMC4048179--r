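---
title: "Structured association mapping with structmap: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structured association mapping with structmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structmap)
```

## The problem

An eQTL study measures, on the same individuals, genotypes at many loci
(an $n \times J$ dosage matrix $X$), genome-wide expression traits (an
$n \times K$ matrix $Y$), and often a panel of clinical traits (an
$n \times q$ matrix $Z$). Single-marker tests treat every (SNP, trait)
pair in isolation and ignore two powerful structures: linkage
disequilibrium groups nearby SNPs, and co-expression groups genes into
modules that respond to shared regulators. structmap implements a family
of sparse multivariate, multi-task regression models that inject this
structure into the penalty of a penalized least-squares problem

$$\min_B \tfrac12 \lVert Y - XB \rVert_F^2 + \Omega(B),$$

so that co-occurring weak signals, individually indistinguishable from
noise, become jointly significant. All solvers use this
$\tfrac12\lVert\cdot\rVert_F^2$ loss convention (no $1/n$ factor);
penalty weights are quoted on that scale, and inputs are z-scored by
default so penalties are comparable across columns and the intercept is
absorbed by centering.

## The model family

* **Lasso** — $\Omega = \lambda \lVert B \rVert_1$; the unstructured
  baseline. Solved by cyclic coordinate descent on the Gram matrices with
  exact soft-threshold zeros.
* **Group lasso** (`fitGroupLasso`) — $\lambda \sum_{k}\sum_g w_g
  \lVert B_{G_g,k}\rVert_2$ over SNP groups $G_g$ (LD blocks, pathways):
  a group is selected or dropped as a whole, per trait. Block coordinate
  descent with exact group updates via the eigendecomposition of
  $X_g^\top X_g$ and a secular equation.
* **Graph-guided fused lasso** (`fitGFLasso`) — adds
  $\gamma \sum_{(m,l)\in E} w_{ml} \sum_j |B_{jm} - s_{ml} B_{jl}|$ over
  the edges of a trait relevance network: coefficients of correlated
  traits are driven to similar magnitude, so a SNP is selected jointly
  for a whole module. The unsigned variant ($s = 1$) is the default; the
  signed variant ($s = \mathrm{sign}(r)$) fuses negatively correlated
  traits to opposite-sign coefficients.
* **Tree-guided group lasso** (`fitTreeLasso`) — a hierarchy of L2 norms
  over the subtrees of a trait dendrogram, leaves contributing weighted
  L1 terms; tightly merged subtrees are penalized mostly as a group,
  loose ones per trait.
* **Adaptive multi-task lasso** (`fitAMTL`) — per-SNP penalty scales that
  are log-linear in genomic annotations (exon, binding site,
  conservation, ...), learned together with $B$ by alternating descent;
  annotated SNPs that carry signal earn smaller penalties.
* **Multi-population group lasso** (`fitMPGL`) — one coefficient vector
  per population for a single trait, coupled by an L2 norm per SNP:
  associations are discovered per population (different magnitudes, even
  opposite signs) while borrowing strength across populations for
  selection.
* **Structured input–output regression** (`fitStructIO`) — both SNP
  groups and trait groups at once, via an L1/L2 penalty over
  SNP-group × trait-group blocks plus elementwise L1.
* **Two-graph fused lasso** (`fitGGFLasso`) and the two-stage pipeline
  (`runTwoStage`) — stage 1 maps SNPs to expression with GFlasso; stage 2
  regresses clinical traits on the *measured* expression matrix with
  fusion along both the gene network (rows) and the trait network
  (columns). SNP–gene–trait triplets are the support product of the two
  stages.

P-values for these penalized fits are deliberately out of scope; the
single-marker tests (`singleMarkerTest`) provide the classical
test-based view, with the naive p < 1e-3 screening convention flagged as
such and BH q-values reported alongside.

## Optimizers and numerical choices

Three engines cover the family:

1. **Coordinate descent on Gram matrices** (C++): lasso, weighted lasso,
   the L1 + row-L2 composite (AMTL inner step), group lasso, MPGL.
   Convergence is declared when the relative objective change per sweep
   falls below `tol` (default 1e-6 to 1e-8 depending on the model;
   tighten for reference-quality solutions). Cyclic update order is fixed
   by column index.
2. **Variational (half-quadratic) coordinate descent** for the fusion
   models: each fusion term $w\,|x|$ is smoothed to $w\sqrt{x^2 +
   \varepsilon^2}$ and majorized by a quadratic at the current iterate,
   so every sweep is exact coordinate minimization with soft-threshold
   zeros for the L1 part. $\varepsilon$ is driven from $10^{-1}$ down to
   `eps` (default 1e-6) by continuation with warm starts. Two properties
   matter here: the recorded objective trace is the *smoothed* objective,
   which the majorize–minimize structure makes monotone (the exact and
   smoothed objectives differ by at most $\varepsilon \sum_e w_e$); and a
   hard clamp instead of smoothing would freeze exactly-fused coordinates
   (the quadratic coupling $w/d$ diverges), which the continuation
   avoids.
3. **Smoothing proximal gradient (SPG)** for the tree penalty (and as a
   cross-checking second solver for GFlasso): the non-separable penalty
   part is smoothed through its dual with parameter $\mu$ (default
   $\mu = \epsilon/(2D)$ with target gap $\epsilon = 10^{-4}$ and $D$ the
   squared dual-ball radius), and monotone FISTA with Lipschitz steps
   minimizes the composite, again with continuation on $\mu$. The leaf
   (L1) part keeps its exact prox, so those zeros are exact; smoothed
   group coefficients are post-thresholded at 1e-8 and the threshold is
   recorded in the fit's provenance. An exact-prox engine
   (`engine = "prox"`, hierarchical group shrinkage applied children
   before parents) is available as an independent check.

Tree node weights follow the standard recursion: an internal node at
normalized merge height $h_v$ carries $s_v = 1 - h_v$ and passes
$g_v = h_v$ down, so nodeWeight$(v) = s_v \prod_{a \supset v} g_a$ and
each leaf gets $\prod_a g_a$. The scheme is pluggable
(`traitTree(weights = ...)`) because the literature admits several
conventions.

The adaptive penalty scales of AMTL are normalized to mean one across
SNPs (a softmax in $-\theta^\top f_j$). This normalization is what makes
the weight estimation well posed: the overall penalty scale is not
identifiable from the joint objective, and without the constraint the
weights of zero-coefficient SNPs diverge. A small ridge (default
$\tau = 0.1$) adds curvature when features separate perfectly.

## Structure builders

Trait networks come from thresholded absolute correlation, soft-power
(scale-free) adjacency $|r|^\beta$ with $\beta$ the smallest grid value
whose connectivity distribution reaches the target log–log fit
($R^2 \ge 0.8$ on 10 log-spaced bins by default), or the graphical lasso
(implemented in-package as block coordinate descent with lasso
subproblems; edge weight = absolute partial correlation). Edge weights
are magnitudes; the signed value is retained for the signed fusion
variant.

Modules are found by a dynamic program over the cuts of the trait
dendrogram. Each internal node is scored by its total internal edge
weight divided by its size (half the mean internal degree). We chose
this connectivity score over raw edge density deliberately: density is
maximized by small sub-cliques of a module (the tightest pairs merge
first), whereas the per-trait connectivity of a homogeneous module grows
with its size, so the DP recovers whole planted modules rather than
their cores, while merging unrelated modules or attaching loose traits
still lowers the score. The DP maximizes the total score of up to M
disjoint (non-nested) nodes.

Enrichment is a one-sided hypergeometric tail with BH correction, with
terms treated as flat sets (no ontology propagation); the same machinery
serves GO-style annotations and eQTL enrichment via
`associationTermMap`.

## Model selection

`crossValidate` implements the linear (one-axis-at-a-time) search:
$\lambda$ is tuned on its grid with $\gamma = 0$, then $\gamma$ at the
selected $\lambda$; the error is the mean held-out squared prediction
error per cell (averaged over traits, so the scale is trait-count
invariant). Data are standardized once before splitting. The default
selection rule is the one-standard-error rule — the strongest
regularization within one SE of the error minimum — because the fits are
read for their support: the error-minimizing $\lambda$ systematically
overselects, which both dilutes the lasso's support and lets the fusion
penalty drag false positives across modules. `rule = "min"` restores the
error minimizer. Ties always prefer the stronger regularization.

## The synthetic panel

`simConfig`/`simulateDataset` generate the three-layer panel all
recovery experiments use. Defaults: n = 200 haploid samples; J = 100
SNPs in LD blocks of 10 with adjacent-SNP correlation 0.5 (a first-order
Markov copy process, giving geometric decay — moderate LD typical of a
sparse marker panel; block frequencies are Balding–Nichols-dispersed
across populations when `nPops > 1`); K = 50 genes in 5 modules with
within-module correlation 0.6 from a shared latent factor; q = 10
clinical traits. One causal SNP in each of the first three LD blocks
drives all genes of modules 1–3 and a hotspot SNP in block 4 drives the
last 30 genes, with heterogeneous per-gene effects (alternating 0.8 and
0.2 on the standardized scale): effect heterogeneity is both realistic —
a regulator's downstream effects vary — and the regime where structure
helps, since uniformly strong effects are fully recoverable one gene at
a time. The gene-to-trait layer routes modules 1–2 to traits 1–3
(effect 0.4 per gene), deliberately disjoint from the hotspot targets so
the planted chains are not confounded with pure trans regulation. Noise
is unit Gaussian in both layers.

What the generator does **not** emulate: coalescent-accurate LD,
epistasis, case/control ascertainment, batch structure, or heavy-tailed
expression noise. Passing recovery tests on this panel demonstrates that
the estimators exploit modular structure as designed, not that they are
robust to everything real data do.

## The standard experiments

The `benchmark*` functions freeze the evaluation protocols (the
acceptance script and the test suite call exactly these):

* `benchmarkSupportRecovery` — 20 seeds of the default panel; lasso and
  GFlasso hyperparameters selected by 10-fold CV (linear search, 1-SE
  rule; $\lambda$ grid = $\lambda_{\max}\cdot\{.1,.2,.3,.45,.65,.9\}$,
  $\gamma$ grid = $\lambda^\ast\cdot\{.1,.3,1,3\}$; network = correlation
  threshold 0.4); scored by F1 on the exact support of $B$. The planted
  hotspot must be flagged by `detectHotspots` (more than 20 associated
  genes) in the GFlasso fit.
* `benchmarkChainRecovery` — 20 seeds with uniform strong effects (0.8);
  the two-stage pipeline with fixed strong penalties
  ($\lambda_1 = 0.65\,\lambda_{\max}$, $\gamma_1 = 0.3\,\lambda_1$;
  $\lambda_2 = 0.45\,\lambda_{\max,2}$, $\gamma_2 = 0.3\,\lambda_2$).
  Fixed fractions are used here rather than CV because the chain
  experiment probes the pipeline, and CV's seed-to-seed variability in
  $\lambda$ would dominate the comparison; the fractions sit where the
  1-SE rule typically lands. Recovered triplets are matched to planted
  chains under the 2 Mb single-linkage merge convention — the same rule
  `mergeNearbySNPs` applies when counting associations — so an LD
  neighbour of the causal SNP counts as the same association.
* `benchmarkTestCalibration` — 10 000 independent null replicates
  (n = 100) for the Wald, t, likelihood-ratio and heterogeneity tests.
* `benchmarkPopulationRecovery` — 20 seeds of a 4-population panel
  (Fst = 0.2, n = 200, J = 1000 — a panel wide enough for eigenvector
  separation, as stratification analyses use genome-wide markers),
  scored by adjusted Rand index of PCA + k-means labels against truth.

A small worked example:

```{r example, eval = FALSE}
cfg <- simConfig(seed = 1)
d <- simulateDataset(cfg)
net <- correlationNetwork(d$expression, threshold = 0.4)
fit <- fitGFLasso(d$genotypes, d$expression, net, lambda = 50, gamma = 15)
detectHotspots(fit)[1:3, ]
classifyCisTrans(fit, snpMap(d$genotypes), geneMap(d$expression))[1:5, ]
```

## Design decisions on open points

* **Genotype coding**: both 0/1 (haploid cross) and 0/1/2 (diploid) are
  supported and recorded; standardization makes the fits invariant to
  affine recoding. Missing genotypes are rejected at load — only trait
  imputation (`imputeKNN`, k = 10 by default, root-mean-square distance
  over mutually observed traits, ties by sample order) is provided.
* **Fusion weights**: edge weight magnitude enters the penalty
  ($f(r) = |r|$); the signed variant is available but off by default,
  since fusing anticorrelated traits to opposite signs helps only when
  the network's signs are trustworthy.
* **CV error**: averaged (not summed) over traits.
* **Heterogeneity test**: the population-stratified comparison uses the
  genotype × population interaction F-test in a pooled linear model as
  the documented stand-in for a dedicated by-population statistic, and
  is labeled as such in the output. Its power depends strongly on the
  genotype variance (a haploid 0/1 marker carries at most variance 0.25),
  so moderate cross-population differences need large samples; the test
  suite verifies reliable detection for a 1-SD effect confined to one of
  four populations at n = 400.
* **Gene position**: the transcription start anchors cis/trans distance;
  chromosome X exclusion is an optional filter (off by default).
* **Population assignment**: model-based admixture inference is out of
  scope; eigen-analysis plus k-means (20 restarts, labels canonicalized
  by cluster size) covers the stratified analyses, and external
  assignments can be supplied.

## Problem sizes and reproducibility

All simulation experiments run at desk scale (the sizes quoted above;
the solver cores are compiled, and a full support-recovery benchmark
takes a few minutes on one CPU). Every generator and every stochastic
procedure (CV folds, k-means restarts) is deterministic given its seed;
`scripts/acceptance.R --seed S --out f.json` re-runs the whole battery
from scratch and writes the headline numbers.

## Known limitations

Exact-zero support is an imperfect readout for fusion models: at the
optimum, a fused module is selected or dropped as a block, so isolated
evidence on one gene can pull small nonzero coefficients across its
module. The support-recovery experiment therefore reports F1 at the
CV-selected regularization, where this effect is part of the measured
trade-off. P-values for the penalized fits, overlapping groups,
non-linear losses and kinship/mixed-model corrections are out of scope.
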