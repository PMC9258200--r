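#' Phenotype-conditional Jaccard similarity of two variants
#'
#' The carrier sets of the two variants are restricted to patients of one
#' phenotype class; the statistic is the size of their intersection over the
#' size of their union. An empty union (neither variant carried in the class)
#' yields 0: a pair never seen in a class carries no co-occurrence evidence.
#'
#' @param a,b variant ids.
#' @param x a [cohort] with phenotype.
#' @param k phenotype class, 0 or 1.
#' @return A value in `[0, 1]`.
#' @export
jcs <- function(a, b, x, k) {
  if (is.null(x$phenotype)) stop_("cohort has no phenotype")
  for (v in c(a, b)) {
    if (!v %in% x$variants) stop_("unknown variant '%s'", v)
  }
  idx <- x$phenotype == k
  ca <- x$carriers[idx, a] == 1L
  cb <- x$carriers[idx, b] == 1L
  u <- sum(ca | cb)
  if (u == 0L) 0 else sum(ca & cb) / u
}

#' Level of association (LOA) between two variants
#'
#' Natural log of the ratio of the pair's Jaccard similarity among cases to
#' that among controls, with an additive smoothing constant on both terms so
#' the ratio stays finite when one class shows no co-occurrence:
#' `log((JCS1 + eps) / (JCS0 + eps))`. Positive values mean the pair
#' co-occurs preferentially in cases, negative the opposite, and 0 means no
#' phenotype-differential co-occurrence. The additive form keeps the
#' statistic symmetric in (a, b), exactly 0 for equal similarities, and
#' antisymmetric under swapping the phenotype labels.
#'
#' @inheritParams jcs
#' @param epsilon smoothing constant, > 0 (default 1e-3).
#' @return A finite real number.
#' @export
loa <- function(a, b, x, epsilon = 1e-3) {
  if (!is.numeric(epsilon) || epsilon <= 0) stop_("'epsilon' must be > 0")
  log((jcs(a, b, x, 1L) + epsilon) / (jcs(a, b, x, 0L) + epsilon))
}

#' Per-gene association matrix of pairwise LOA values
#'
#' Builds the symmetric adjacency matrix of the gene's intragenic association
#' network: entry (i, j) is the LOA of variants i and j, the diagonal is 0
#' by convention (self-association is uninformative). Pairwise intersection
#' and union counts are computed by class-restricted cross-products of the
#' binary carrier matrix, so the cost is one matrix product per phenotype
#' class.
#'
#' @param gene_id gene label carried on the result.
#' @param variants character vector (length >= 2) of the gene's variant ids.
#' @param x a [cohort] with phenotype.
#' @param epsilon smoothing constant passed to the LOA definition.
#' @return An object of class `association_matrix` with fields `gene_id`,
#'   `variants`, `loa` (symmetric matrix, zero diagonal) and `epsilon`.
#' @export
build_ajm <- function(gene_id, variants, x, epsilon = 1e-3) {
  if (length(variants) < 2L) {
    stop_("gene '%s' has <2 variants and cannot form an association network",
          gene_id)
  }
  if (!is.numeric(epsilon) || epsilon <= 0) stop_("'epsilon' must be > 0")
  if (is.null(x$phenotype)) stop_("cohort has no phenotype")
  missing <- setdiff(variants, x$variants)
  if (length(missing)) {
    stop_("unknown variant(s): %s", paste(missing, collapse = ", "))
  }
  jcs_class <- function(k) {
    m <- x$carriers[x$phenotype == k, variants, drop = FALSE]
    inter <- crossprod(m)                      # |A n B| per pair
    n_carriers <- diag(inter)
    un <- outer(n_carriers, n_carriers, `+`) - inter
    j <- ifelse(un > 0, inter / un, 0)
    j
  }
  l <- log((jcs_class(1L) + epsilon) / (jcs_class(0L) + epsilon))
  diag(l) <- 0
  dimnames(l) <- list(variants, variants)
  structure(list(gene_id = gene_id, variants = variants, loa = l,
                 epsilon = epsilon),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("<association_matrix> gene %s, %d variants, epsilon %g\n",
              x$gene_id, length(x$variants), x$epsilon))
  invisible(x)
}

#' Non-negative transform of an association matrix
#'
#' Elementwise exponential of the LOA matrix. Every entry becomes strictly
#' positive (the diagonal becomes 1), which is what non-negative matrix
#' factorization requires and what the weighted random walks use as
#' transition weights.
#'
#' @param ajm an `association_matrix`.
#' @return A positive matrix with unit diagonal and the same dimnames.
#' @export
to_ajnm <- function(ajm) {
  stopifnot(inherits(ajm, "association_matrix"))
  exp(ajm$loa)
}

#' Write an association matrix
#'
#' `write_ajm()` writes the full per-gene matrix as TSV (header =
#' variant order); `write_ajm_edges()` writes the upper-triangle edge list
#' (gene, variant_i, variant_j, loa).
#'
#' @param ajm an `association_matrix`.
#' @param path output file.
#' @export
write_ajm <- function(ajm, path) {
  df <- data.frame(variant_id = ajm$variants, ajm$loa, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ajm
#' @export
write_ajm_edges <- function(ajm, path) {
  idx <- which(upper.tri(ajm$loa), arr.ind = TRUE)
  df <- data.frame(gene_id = ajm$gene_id,
                   variant_i = ajm$variants[idx[, 1L]],
                   variant_j = ajm$variants[idx[, 2L]],
                   loa = ajm$loa[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
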