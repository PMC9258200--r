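#' Weighted random walks over a gene's association network
#'
#' Starting `walks_per_node` times from every node, a walk of `walk_length`
#' nodes is sampled; at each step the next node is drawn among the other
#' nodes with probability proportional to `exp(loa[current, other])` — the
#' same non-negativity transform used for matrix factorization, so transition
#' probability is monotone in the level of association. Self-transitions are
#' excluded. Deterministic given `seed`.
#'
#' @param ajm an `association_matrix` with >= 2 variants.
#' @param walks_per_node walks started from each node (default 10).
#' @param walk_length nodes per walk, including the start (default 10).
#' @param seed integer seed.
#' @return An object of class `walk_corpus`: `walks` is an integer matrix
#'   (`walks_per_node * n_nodes` rows, `walk_length` columns) of 1-based
#'   node indices into `variants`.
#' @export
sample_walks <- function(ajm, walks_per_node = 10L, walk_length = 10L,
                         seed = 1L) {
  stopifnot(inherits(ajm, "association_matrix"))
  n <- length(ajm$variants)
  if (n < 2L) stop_("need >= 2 nodes to walk")
  w <- exp(ajm$loa)
  diag(w) <- 0
  prob <- w / rowSums(w)
  n_walks <- walks_per_node * n
  walks <- matrix(0L, nrow = n_walks, ncol = walk_length)
  walks[, 1L] <- rep(seq_len(n), each = walks_per_node)
  with_seed(seed, {
    for (step in seq_len(walk_length - 1L)) {
      cur <- walks[, step]
      walks[, step + 1L] <- vapply(cur, function(i) {
        sample.int(n, 1L, prob = prob[i, ])
      }, integer(1L))
    }
  })
  structure(list(walks = walks, variants = ajm$variants,
                 gene_id = ajm$gene_id, walks_per_node = walks_per_node,
                 walk_length = walk_length),
            class = "walk_corpus")
}

new_embedding_table <- function(gene_id, backend, vectors, params) {
  structure(list(gene_id = gene_id, backend = backend,
                 dim = ncol(vectors), vectors = vectors, params = params),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> gene %s, backend %s, %d x %d\n",
              x$gene_id, x$backend, nrow(x$vectors), x$dim))
  invisible(x)
}

#' SkipGram embedding of a walk corpus (LCW-SG backend)
#'
#' Treats each walk as a sentence and each variant as a word, and trains
#' SkipGram with negative sampling (word2vec-style SGD, dynamic context
#' window, linear learning-rate decay). No minimum-count pruning is applied,
#' so every node keeps a vector. Training is single-threaded and driven by
#' R's RNG, so results are exactly reproducible given the seed.
#'
#' @param corpus a `walk_corpus` from [sample_walks()].
#' @param dim embedding dimension (default 8).
#' @param window maximum context window (default 5).
#' @param epochs passes over the corpus (default 5).
#' @param seed integer seed.
#' @param negative negative samples per positive pair (default 5).
#' @param alpha,min_alpha initial / floor learning rate.
#' @return An `embedding_table` with backend `"lcw_sg"`.
#' @export
embed_skipgram <- function(corpus, dim = 8L, window = 5L, epochs = 5L,
                           seed = 1L, negative = 5L, alpha = 0.025,
                           min_alpha = 1e-4) {
  stopifnot(inherits(corpus, "walk_corpus"))
  if (nrow(corpus$walks) == 0L) stop_("empty walk corpus")
  n <- length(corpus$variants)
  vec <- with_seed(seed, {
    sg_train_cpp(corpus$walks, n, as.integer(dim), as.integer(window),
                 as.integer(epochs), as.integer(negative), alpha, min_alpha)
  })
  rownames(vec) <- corpus$variants
  colnames(vec) <- paste0("v", seq_len(ncol(vec)))
  new_embedding_table(corpus$gene_id, "lcw_sg", vec,
                      list(dim = dim, window = window, epochs = epochs,
                           negative = negative, alpha = alpha,
                           min_alpha = min_alpha, seed = seed,
                           walks_per_node = corpus$walks_per_node,
                           walk_length = corpus$walk_length))
}

#' PCA embedding of an association matrix (GMF-PCA backend)
#'
#' Rows of the LOA matrix are projected onto the top principal components
#' after column centering. Component signs are fixed by forcing the
#' largest-magnitude loading of each component positive, so results do not
#' depend on the underlying eigensolver's sign choices. When fewer than
#' `dim` components exist (tiny genes or degenerate matrices) the embedding
#' is padded with zero columns and a warning is raised.
#'
#' @param ajm an `association_matrix`.
#' @param dim number of components kept (default 2).
#' @return An `embedding_table` with backend `"gmf_pca"`.
#' @export
embed_pca <- function(ajm, dim = 2L) {
  stopifnot(inherits(ajm, "association_matrix"))
  n <- length(ajm$variants)
  pr <- stats::prcomp(ajm$loa, center = TRUE, scale. = FALSE)
  keep <- pr$sdev > 1e-12
  m <- min(dim, sum(keep))
  vec <- matrix(0, nrow = n, ncol = dim,
                dimnames = list(ajm$variants, paste0("v", seq_len(dim))))
  if (m >= 1L) {
    scores <- pr$x[, seq_len(m), drop = FALSE]
    rot <- pr$rotation[, seq_len(m), drop = FALSE]
    flip <- vapply(seq_len(m), function(j) {
      sign(rot[which.max(abs(rot[, j])), j]) < 0
    }, logical(1L))
    scores[, flip] <- -scores[, flip, drop = FALSE]
    vec[, seq_len(m)] <- scores
  }
  if (m < dim) {
    warning(sprintf("gene %s: only %d informative component(s); padding to dim %d with zeros",
                    ajm$gene_id, m, dim))
  }
  new_embedding_table(ajm$gene_id, "gmf_pca", vec,
                      list(dim = dim, n_components = m))
}

#' NMF embedding of an association matrix (GMF-NMF backend)
#'
#' The strictly positive exponential transform of the LOA matrix
#' ([to_ajnm()]) is factorized as `A ~ W H` with `W, H >= 0` by multiplicative
#' updates minimizing the Frobenius reconstruction error; variant i's vector
#' is row i of `W`. Initialization is uniform random scaled to the data, so
#' the factorization is deterministic given `seed`.
#'
#' @param ajm an `association_matrix`.
#' @param dim factorization rank (default 2).
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum multiplicative-update iterations (default 200).
#' @param tol stop when the relative decrease of the reconstruction error
#'   falls below this (default 1e-4, checked every 10 iterations).
#' @return An `embedding_table` with backend `"gmf_nmf"`; the achieved
#'   relative reconstruction error is stored in `params$rel_error`.
#' @export
embed_nmf <- function(ajm, dim = 2L, seed = 1L, max_iter = 200L,
                      tol = 1e-4) {
  stopifnot(inherits(ajm, "association_matrix"))
  a <- to_ajnm(ajm)
  n <- nrow(a)
  scale0 <- sqrt(mean(a) / dim)
  init <- with_seed(seed, {
    list(w = matrix(stats::runif(n * dim), n, dim) * scale0,
         h = matrix(stats::runif(dim * n), dim, n) * scale0)
  })
  w <- init$w
  h <- init$h
  eps <- 1e-12
  norm_a <- sqrt(sum(a^2))
  err_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, a) / (crossprod(w) %*% h + eps))
    w <- w * (a %*% t(h) / (w %*% tcrossprod(h) + eps))
    if (it %% 10L == 0L || it == max_iter) {
      err <- sqrt(sum((a - w %*% h)^2)) / norm_a
      if (is.finite(err_prev) && abs(err_prev - err) < tol) {
        converged <- TRUE
        break
      }
      err_prev <- err
    }
  }
  if (!converged && max_iter > 20L) {
    warning(sprintf("gene %s: NMF did not converge within %d iterations (rel. error %.3g); returning best iterate",
                    ajm$gene_id, max_iter, err_prev))
  }
  rownames(w) <- ajm$variants
  colnames(w) <- paste0("v", seq_len(dim))
  rel_error <- sqrt(sum((a - w %*% h)^2)) / norm_a
  new_embedding_table(ajm$gene_id, "gmf_nmf", w,
                      list(dim = dim, seed = seed, max_iter = max_iter,
                           tol = tol, rel_error = rel_error))
}

#' Write an embedding table as TSV (gene, variant, v1..vd)
#' @param table an `embedding_table`.
#' @param path output file.
#' @export
write_embedding <- function(table, path) {
  df <- data.frame(gene_id = table$gene_id,
                   variant_id = rownames(table$vectors),
                   table$vectors, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
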