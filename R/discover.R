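new_module_candidate <- function(gene_id, variants, approach, index) {
  structure(list(module_id = sprintf("%s/%s/%02d", gene_id, approach, index),
                 gene_id = gene_id, approach = approach,
                 variants = as.character(variants)),
            class = "module_candidate")
}

#' @export
print.module_candidate <- function(x, ...) {
  cat(sprintf("<module_candidate> %s (%d variants)\n", x$module_id,
              length(x$variants)))
  invisible(x)
}

#' Cluster variant embeddings into module candidates
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward linkage by
#' default) of the embedding vectors, cut at every k in
#' `[k_min, min(k_max, n - 1)]`; the cut maximizing the mean silhouette width
#' is kept and each cluster becomes one module candidate. Ties are broken
#' toward the smaller k. Genes with fewer than 3 variants (or with all
#' vectors coincident, where silhouettes are undefined) yield a single
#' whole-gene candidate so every gene still contributes a candidate.
#'
#' @param table an `embedding_table`.
#' @param k_min,k_max scanned range of cluster counts (defaults 2 and 20).
#' @param linkage `"ward"` (mapped to hclust's "ward.D2"), or any method
#'   name `stats::hclust` accepts.
#' @return A list of `module_candidate` objects; attributes `k` and
#'   `silhouette` record the selected cut and its mean silhouette width
#'   (`NA` for degenerate genes).
#' @export
cluster_embeddings <- function(table, k_min = 2L, k_max = 20L,
                               linkage = "ward") {
  stopifnot(inherits(table, "embedding_table"))
  x <- table$vectors
  n <- nrow(x)
  if (n < 2L) stop_("need >= 2 vectors to cluster")
  whole_gene <- function() {
    out <- list(new_module_candidate(table$gene_id, rownames(x),
                                     table$backend, 1L))
    attr(out, "k") <- 1L
    attr(out, "silhouette") <- NA_real_
    out
  }
  if (n < 3L) return(whole_gene())
  d <- stats::dist(x)
  if (max(d) < 1e-12) return(whole_gene())
  method <- if (identical(linkage, "ward")) "ward.D2" else linkage
  hc <- stats::hclust(d, method = method)
  ks <- seq.int(k_min, min(k_max, n - 1L))
  cuts <- lapply(ks, function(k) stats::cutree(hc, k = k))
  sil <- vapply(cuts, function(cl) {
    s <- cluster::silhouette(cl, d)
    mean(s[, "sil_width"])
  }, numeric(1L))
  best <- which.max(sil)  # ties resolve to the smallest k
  cl <- cuts[[best]]
  out <- lapply(sort(unique(cl)), function(g) {
    new_module_candidate(table$gene_id, rownames(x)[cl == g],
                         table$backend, g)
  })
  attr(out, "k") <- ks[best]
  attr(out, "silhouette") <- sil[best]
  out
}

#' Whole-gene control modules (CTRL-GLA)
#'
#' One candidate per gene containing every observed variant: the passive
#' baseline that does not attempt to identify structure within genes.
#'
#' @param map a [gene_map].
#' @return A list of `module_candidate` objects, one per gene.
#' @export
modules_gla <- function(map) {
  stopifnot(inherits(map, "gene_map"))
  unname(lapply(names(map), function(g) {
    new_module_candidate(g, map[[g]], "ctrl_gla", 1L)
  }))
}

#' Single-variant control modules (CTRL-INV)
#'
#' One singleton candidate per observed variant. Downstream scoring of these
#' candidates uses the variant's carrier status directly as the activation
#' status, measuring each variant's own phenotype association — the ceiling
#' an ideal module-discovery algorithm could reach.
#'
#' @param map a [gene_map].
#' @return A list of `module_candidate` objects, one per variant.
#' @export
modules_inv <- function(map) {
  stopifnot(inherits(map, "gene_map"))
  out <- list()
  for (g in names(map)) {
    for (i in seq_along(map[[g]])) {
      out[[length(out) + 1L]] <- new_module_candidate(g, map[[g]][i],
                                                      "ctrl_inv", i)
    }
  }
  out
}

#' Write module candidates as JSON lines
#' @param candidates list of `module_candidate` objects.
#' @param path output file.
#' @export
write_candidates <- function(candidates, path) {
  lines <- vapply(candidates, function(m) {
    jsonlite::toJSON(list(module_id = m$module_id, gene = m$gene_id,
                          approach = m$approach, variants = m$variants),
                     auto_unbox = TRUE)
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}
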