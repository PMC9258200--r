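# varmodnet

Discovering **intragenic functional modules of genomic variants** associated
with a binary phenotype, by representation learning on phenotype-conditional
co-occurrence networks.

Genome-wide association studies score variants one at a time, which misses
phenotypes driven by *sets* of variants within a gene acting together.
`varmodnet` addresses this for case/control cohorts (the motivating setting
is early- vs late-onset disease in a large cancer cohort): it quantifies how
differentially every pair of variants within a gene co-occurs between cases
and controls, learns vector representations of the variants from the
resulting per-gene networks, clusters those vectors into *module
candidates*, and tests each candidate's association with the phenotype —
with a train/test protocol that measures how reproducible each discovery
strategy is.

## The model

For variants *A*, *B* and binary phenotype *X* (1 = case), the
**level of association** is the log-ratio of class-restricted Jaccard
similarities of the two carrier sets:

```
JCS(A, B | X = k) = |carriers(A) ∩ carriers(B)| / |carriers(A) ∪ carriers(B)|   (patients with X = k)
LOA(A, B | X)     = log( (JCS(A,B|X=1) + ε) / (JCS(A,B|X=0) + ε) )
```

A positive LOA means the pair co-occurs preferentially in cases. The
additive smoothing constant ε (default 1e-3) keeps the ratio finite when a
class shows no co-occurrence; an empty union gives JCS = 0. Per gene, the
symmetric matrix `AJM[i, j] = LOA(i, j | X)` (zero diagonal) defines an
association network over the gene's variants, and `AJNM = exp(AJM)` is its
strictly positive transform.

Three interchangeable backends embed each gene's variants:

* **LCW-SG** — 10 weighted random walks of length 10 from every node
  (transition probability ∝ `exp(LOA)`), fed to SkipGram with negative
  sampling (one vector per variant);
* **GMF-PCA** — rows of AJM projected on the top principal components
  (default 2, deterministic sign convention);
* **GMF-NMF** — non-negative factorization `AJNM ≈ W·H` (default rank 2);
  variant *i*'s vector is row *i* of `W`.

Embeddings are cut by agglomerative (Ward) clustering, with the number of
clusters *k* chosen to maximize the mean silhouette width; each cluster is a
module candidate. A candidate *m* is scored through its activation:

```
MAL(p, m) = |R_m ∩ F_p| / |R_m|          (fraction of module variants patient p carries)
thr(m)    = mean of MAL over all patients
MAS(p, m) = 1 if MAL(p, m) > thr(m), else 0
```

Cross-tabulating activation against phenotype gives a 2×2 table
(a = activated cases, b = activated controls, c = inactivated cases,
d = inactivated controls); **FEP** is the one-sided (positive) Fisher exact
p-value P(X ≥ a) and **FER** = (a/b)/(c/d) the odds ratio. Two controls
bracket the learned approaches: **CTRL-GLA** treats each whole gene as one
module; **CTRL-INV** scores every single variant by its carrier status (the
ceiling an ideal algorithm could reach).

The benchmark splits the cohort in half (stratified by phenotype), discovers
candidates on the training split only, accepts candidates with FEP < 0.05 on
train, re-tests the accepted ones on the held-out split, and reports the
**acceptance rate** (accepted/candidates) and **reproduction rate**
(reproduced/accepted) for all five approaches.

## Worked example

Simulate a 2,000-patient cohort (10% cases) with one gene of 12 variants
carrying two planted modules of 6, run the NMF backend, and score the
discovered candidates:

```r
library(varmodnet)

cfg <- sim_config_strong(seed = 42)
sim <- simulate_cohort(cfg)
sim$cohort
#> <cohort> 2000 patients x 12 variants; phenotype: 200 cases / 1800 controls

map  <- sim_gene_map(cfg)
cand <- run_approach("gmf_nmf", sim$cohort, map, vmn_config(seed = 42))
score_modules(cand, sim$cohort)[, c("module_id", "n_variants", "a", "b", "c", "d", "fep", "fer")]
#>           module_id n_variants   a   b  c    d          fep       fer
#> 1 GENE01/gmf_nmf/01          6 143 290 57 1510 1.451710e-58 13.062916
#> 2 GENE01/gmf_nmf/02          6 128 299 72 1501 5.543038e-44  8.924563
```

The two discovered candidates are exactly the two planted modules: each is
activated in ~70% of cases versus ~17% of controls (a/(a+c) vs b/(b+d)),
giving odds ratios of 13.1 and 8.9 and vanishing one-sided exact p-values.
The full five-approach reproducibility benchmark on the same cohort:

```r
evaluate_all(sim$cohort, map, vmn_config(seed = 42))
#>   approach n_candidates n_accepted_train acceptance_rate n_reproduced_test reproduction_rate
#> 1   lcw_sg            2                2               1                 2                 1
#> 2  gmf_nmf            3                3               1                 3                 1
#> 3  gmf_pca            2                2               1                 2                 1
#> 4 ctrl_gla            1                1               1                 1                 1
#> 5 ctrl_inv           12               12               1                12                 1
```

With a planted effect this strong every approach's discoveries reproduce on
the held-out split; on a null cohort (`sim_config_null()`) acceptance rates
fall to the 0.05 significance level.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/varmodnet.R simulate --config sim.yaml --out cohort/
Rscript inst/cli/varmodnet.R evaluate --carriers cohort/carriers.tsv \
    --phenotype cohort/phenotype.tsv --genemap cohort/gene_map.tsv \
    --seed 1 --out report/
```

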