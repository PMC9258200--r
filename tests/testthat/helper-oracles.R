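# Independent brute-force oracles and small fixtures shared across tests.
# The oracles deliberately use plain set arithmetic / enumeration, not the
# package's vectorized code paths.

# Jaccard similarity by explicit set operations on patient-id sets.
oracle_jcs <- function(carriers, phenotype, a, b, k) {
  pats <- rownames(carriers)[phenotype == k]
  set_a <- pats[carriers[pats, a] == 1L]
  set_b <- pats[carriers[pats, b] == 1L]
  u <- union(set_a, set_b)
  if (length(u) == 0L) 0 else length(intersect(set_a, set_b)) / length(u)
}

oracle_loa <- function(carriers, phenotype, a, b, epsilon) {
  log((oracle_jcs(carriers, phenotype, a, b, 1L) + epsilon) /
        (oracle_jcs(carriers, phenotype, a, b, 0L) + epsilon))
}

# Full matrix by a double loop over the definition.
oracle_ajm <- function(carriers, phenotype, epsilon) {
  vars <- colnames(carriers)
  n <- length(vars)
  m <- matrix(0, n, n, dimnames = list(vars, vars))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        m[i, j] <- oracle_loa(carriers, phenotype, vars[i], vars[j], epsilon)
      }
    }
  }
  m
}

# Upper-tail hypergeometric P(X >= a) by term-wise enumeration with exact
# integer-valued choose() terms (all counts <= 40, so every binomial
# coefficient is an exact double).
oracle_fep <- function(a, b, c, d) {
  n_row <- a + b
  n_col <- a + c
  n_tot <- a + b + c + d
  lo <- max(0L, n_row + n_col - n_tot)
  hi <- min(n_row, n_col)
  xs <- a:hi
  if (a > hi) return(0)
  num <- sum(choose(n_col, xs) * choose(n_tot - n_col, n_row - xs))
  num / choose(n_tot, n_row)
}

# Mean silhouette width computed straight from the definition.
oracle_mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) {
      s[i] <- 0
      next
    }
    a_i <- mean(d[i, setdiff(own, i)])
    b_i <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, numeric(1L)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# Deterministic 8-patient x 4-variant toy cohort used across modules.
toy_cohort <- function() {
  carriers <- matrix(
    c(1L, 1L, 0L, 0L,
      1L, 1L, 0L, 1L,
      0L, 1L, 1L, 0L,
      1L, 0L, 0L, 0L,
      0L, 0L, 1L, 1L,
      1L, 0L, 1L, 0L,
      0L, 1L, 0L, 1L,
      0L, 0L, 0L, 0L),
    nrow = 8L, byrow = TRUE,
    dimnames = list(sprintf("P%d", 1:8),
                    c("chr1:100:A:G", "chr1:200:C:T",
                      "chr1:300:G:A", "chr1:400:T:C")))
  cohort(carriers, phenotype = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
}

# Random small cohort with both phenotype classes present.
rand_cohort <- function(n_pat, n_var, seed) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_pat * n_var, 1L, runif(1, 0.2, 0.7)), n_pat, n_var,
                dimnames = list(sprintf("P%d", seq_len(n_pat)),
                                sprintf("chr1:%d:A:G", 100L * seq_len(n_var))))
    ph <- rbinom(n_pat, 1L, 0.5)
    if (any(ph == 1L) && any(ph == 0L)) return(cohort(m, ph))
  }
}

# Hand-built association matrix (for embedding tests that need controlled
# structure rather than data-derived LOA values).
manual_ajm <- function(loa_matrix, gene_id = "GENE") {
  structure(list(gene_id = gene_id, variants = rownames(loa_matrix),
                 loa = loa_matrix, epsilon = 1e-3),
            class = "association_matrix")
}

# Two-block LOA matrix: strong positive association inside each block,
# strong negative across.
two_block_loa <- function(sizes = c(3L, 3L), within = 2, across = -2) {
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  m <- ifelse(outer(lab, lab, "=="), within, across)
  diag(m) <- 0
  dimnames(m) <- list(sprintf("chr1:%d:A:G", 100L * seq_len(n)),
                      sprintf("chr1:%d:A:G", 100L * seq_len(n)))
  m
}

# Partition labels implied by a candidate list, aligned to `variants`.
candidate_labels <- function(candidates, variants) {
  lab <- integer(length(variants))
  names(lab) <- variants
  for (i in seq_along(candidates)) lab[candidates[[i]]$variants] <- i
  lab
}
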