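---
title: "Methods: phenotype-conditional variant networks, embeddings and module scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-conditional variant networks, embeddings and module scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varmodnet)
```

## The problem and the statistic

`varmodnet` looks for sets of variants within a gene whose *joint* carrier
pattern is associated with a binary phenotype (case = 1, e.g. early-onset
disease). The primitive is the level of association between two variants
$A$ and $B$ given phenotype $X$:

$$\mathrm{JCS}(A,B \mid X{=}k) \;=\;
  \frac{|C_A \cap C_B|}{|C_A \cup C_B|}\Big|_{X=k}, \qquad
\mathrm{LOA}(A,B \mid X) \;=\;
  \log\frac{\mathrm{JCS}(A,B\mid X{=}1) + \varepsilon}
           {\mathrm{JCS}(A,B\mid X{=}0) + \varepsilon},$$

where $C_V$ is the carrier set of variant $V$ restricted to one phenotype
class. LOA is positive when the pair co-occurs preferentially in cases,
negative in the opposite case, and zero when the class-restricted
similarities are equal. Per gene $l$ with variant set $V_l$, the matrix
$\mathrm{AJM}[i,j] = \mathrm{LOA}(i,j \mid X)$ (symmetric, zero diagonal) is
an association network over the gene's variants; its elementwise exponential
$\mathrm{AJNM} = e^{\mathrm{AJM}}$ is strictly positive.

Two numerical choices deserve comment, because the raw log-ratio is
undefined when a class-restricted similarity is zero:

* **Empty union ⇒ JCS = 0.** A pair never carried in a class contributes no
  co-occurrence evidence; treating it as missing (NaN) would silently drop
  edges from the network.
* **Additive smoothing.** Both similarities receive the same additive
  $\varepsilon$ (default $10^{-3}$, configurable everywhere as `epsilon`).
  This keeps every LOA finite, preserves symmetry in $(A,B)$, yields exactly
  0 for equal similarities regardless of $\varepsilon$, and makes the whole
  matrix negate exactly under swapping the phenotype labels — a property the
  test suite asserts to machine precision. The cost is a scale cap: a pair
  seen only in cases saturates at $\log((J_1+\varepsilon)/\varepsilon)$
  rather than $+\infty$. With rare variants (a handful of carriers per
  class) these saturated values (~±3 to ±7) are reached by chance alone,
  which matters for what the synthetic benchmarks can and cannot show (see
  below).

Natural logarithms are used throughout.

## Embedding backends

Each gene's AJM is embedded by one of three backends; all are deterministic
given their seed and never drop a variant.

**LCW-SG** samples, from every node, `walks_per_node = 10` random walks of
`walk_length = 10` nodes. Transition probabilities are proportional to
$e^{\mathrm{LOA}}$ to the other nodes (self-transitions excluded) — the
same non-negativity transform the NMF backend uses, chosen because walk
weights must be nonnegative while LOA is signed, and the exponential is
monotone in LOA. The walk corpus is trained with SkipGram and negative
sampling (dimension 8, window 5, 5 epochs, 5 negatives, linear
learning-rate decay from 0.025), single-threaded and driven by R's RNG so
that a seed fully determines the embedding. These hyperparameters follow
common word2vec practice; only the walk counts are structural (they fix the
corpus size), and all are exposed in `vmn_config()` and recorded in each
`embedding_table` for provenance.

**GMF-PCA** projects the rows of AJM onto the top 2 principal components
after column centering. Eigenvector sign is inherently arbitrary, so each
component is flipped to make its largest-magnitude loading positive; this
makes results identical across platforms and is the only sense in which the
embedding is "up to sign". Genes with fewer informative components than the
requested dimension are zero-padded with a warning.

**GMF-NMF** factorizes AJNM (which is strictly positive, as NMF requires)
as $W H$ with $W, H \ge 0$ by Frobenius multiplicative updates
(rank 2, random uniform initialization scaled to the data, at most 200
iterations, stopping when the relative reconstruction error changes by less
than $10^{-4}$ between 10-iteration checkpoints — the conventional defaults
for this algorithm family). Non-convergence returns the best iterate with a
warning; on unstructured (null) genes the rank-2 error genuinely plateaus
around 0.4–0.5, which is expected, not a failure.

The factorization rank of 2 for both GMF backends reflects that the
discovery target is a small number of blocks per gene; the SkipGram
dimension is independent of it.

## Module discovery and scoring

Embeddings are clustered by agglomerative hierarchical clustering
(Euclidean distance, Ward linkage). Each cut $k \in [2, \min(20, n-1)]$ is
scored by mean silhouette width and the maximizing $k$ is kept, with ties
going to the smaller $k$ (parsimony). Linkage, metric and the scan range
are not forced by the method and are exposed as configuration; Ward is the
default because the learned spaces have compact, roughly isotropic
clusters. Genes with fewer than 3 variants cannot be silhouette-scanned and
yield one whole-gene candidate instead of being dropped, so candidate
counts stay comparable with the whole-gene control. The same fallback
applies when all vectors coincide (silhouettes are undefined).

A module candidate $m$ with variant set $R_m$ is scored on whatever cohort
is being evaluated: the activation level $\mathrm{MAL}(p,m) = |R_m \cap
F_p| / |R_m|$ ($F_p$ = variants of patient $p$), the threshold
$\mathrm{thr}(m)$ = cohort-mean MAL, and the strict binarization
$\mathrm{MAS} = [\mathrm{MAL} > \mathrm{thr}]$. The strictness is kept
exactly as defined, including its degenerate consequence: if every patient
has the same activation level, nobody is activated. Activation ×
phenotype gives the table $(a, b, c, d)$; FEP is the upper-tail
hypergeometric probability $P(X \ge a)$ (only *positive* association is
flagged) and FER $= (a d)/(b c)$, reported honestly as `Inf` when only the
denominator product vanishes and `NaN` when both do (an optional
Haldane–Anscombe +0.5 correction exists, off by default). Raw p-values are
thresholded at $\alpha = 0.05$ with no multiplicity correction, matching
the benchmark design this package implements; a user wanting FDR control
can apply `p.adjust` to the score table.

Two resolved ambiguities:

* **Threshold locality.** The threshold is defined as a mean over "all
  patients in the data"; when train and test splits are scored separately,
  each split uses its own mean. The alternative (freezing the training
  threshold) was rejected because the threshold is part of the scoring
  statistic, not of the discovered hypothesis — the module's *membership*
  is what transfers between splits.
* **Single-variant controls.** CTRL-INV candidates are scored on carrier
  status directly (no threshold): the mean-carrier threshold applied to a
  0/1 column would reproduce carrier status anyway whenever the variant is
  carried by a minority, and the control is defined as measuring each
  variant's own association.

## The evaluation protocol

`evaluate_all()` splits the cohort once, stratified by phenotype: within
each class, `floor(fraction × n)` patients go to train and the remainder to
test, so a class of 3,181 splits 1,590/1,591 at fraction 0.5. Whether the
original benchmark randomized or stratified its split is not documented
beyond its printed class counts; stratified-random reproduces those counts
and is the natural default. Variants carried by no training patient are
dropped (per gene) before discovery, and genes left empty are dropped;
variants reduced to a single observed representative still contribute one
whole-gene candidate. Discovery sees the training split only. All five
approaches share the same split and the same master seed, from which
per-gene, per-backend substreams are derived. Rates are kept as unrounded
count ratios and rounded to 4 decimals only for presentation, because
downstream ratio-of-rates comparisons are only recoverable from the raw
counts. Zero-denominator rates are `NA` sentinels, never 0.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` uses a latent-activation model: each planted module has
a hidden per-patient Bernoulli activation whose rate depends on phenotype
($p_\mathrm{case}$ vs $p_\mathrm{ctrl}$); active patients carry each member
variant with probability $q_\mathrm{active}$, everyone else carries every
variant at a background rate $q_0$. This single mechanism produces both
signatures the LOA statistic targets — within-module co-occurrence *and*
phenotype-conditional enrichment of that co-occurrence — which is why it is
the generator of choice over direct pairwise-correlation constructions.
Draws are organized as one substream per gene derived from the master seed,
so extending a configuration with new genes leaves earlier genes' data
bit-identical.

Two preset study conditions are used by the tests and the acceptance
script:

* **Null condition** (`sim_config_null()`): 2,000 patients, 10% cases, 60
  genes × 10 variants, no planted modules, background rate 0.1. The
  common-variant background keeps activation tables well populated so that
  the discreteness of the exact test does not dominate; acceptance rates
  are then checked against the nominal 0.05 level within 3 binomial
  standard errors per approach.
* **Strong condition** (`sim_config_strong()`): 2,000 patients, 10% cases,
  one gene of 12 variants holding two planted modules of 6
  ($p_\mathrm{case} = 0.6$, $p_\mathrm{ctrl} = 0.05$,
  $q_\mathrm{active} = 0.9$, $q_0 = 0.02$). The two modules carve the
  gene's AJM into blocks with sharply different within- and cross-block
  association levels, making the planted partition identifiable; every
  backend is required to recover it (adjusted Rand index ≥ 0.8) in at
  least 80% of 20 seeds, and the planted modules to reach FEP < 0.05 in at
  least 90%.

The two-module layout is a deliberate design choice. A module planted
against a remainder of *rare background* variants ($q_0 = 0.02$, so ~4
carriers among 200 cases) is not a usable positive control: at those
counts a background variant's class-restricted similarity to the module is
0 or a small positive number essentially at random, and the smoothed
log-ratio then takes saturated values of ±3 that match or exceed the
~0.5 within-module contrast. No clustering method can undo that — the
information is not in the data. The same effect, in milder form, is a known
property of the real statistic on rare variants.

What the generator does **not** emulate: linkage-disequilibrium structure
(carriers are conditionally independent given activation), realistic allele
frequency spectra, population stratification, or covariates. Passing the
recovery benchmarks therefore demonstrates correctness of the pipeline's
machinery on data matching its own model assumptions — not performance on
real cohorts, where LD alone can produce intragenic co-occurrence blocks
with no phenotype relevance.

## Problem sizes and determinism

The shipped tests and the acceptance script run the null condition at 600
candidate variants and the strong condition over 20 seeds; both finish in
well under a minute on a single core, and the same functions scale to
thousands of genes by iterating the per-gene pipeline (the per-gene cost is
one carrier-matrix cross-product per phenotype class plus the embedding).
Every stochastic step — phenotype assignment, carrier draws, walk sampling,
SkipGram SGD, NMF initialization, the cohort split — consumes an explicit
seed or a substream derived from one, and the test suite asserts that
identical configuration plus seed reproduces evaluation reports
byte-for-byte. Multi-worker SkipGram training is deliberately absent: exact
reproducibility was judged worth more than the speedup at these problem
sizes.

## Known limitations

* The smoothing constant bounds, but does not remove, the instability of
  LOA for variant pairs with very few carriers; on rare-variant data the
  network is noisy by construction and downstream modules should be read
  accordingly.
* FER is a raw odds ratio with no confidence interval; use the contingency
  counts if interval estimates are needed.
* The silhouette scan cannot select $k = 1$ or $k = n$; a gene that truly
  is one module (or all singletons) will still be split into at least two
  candidates by the learned approaches, which is one reason the evaluation
  includes the whole-gene and single-variant controls.
* No multiple-testing correction is applied in the benchmark path, by
  design; absolute acceptance counts should not be read as discoveries.
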