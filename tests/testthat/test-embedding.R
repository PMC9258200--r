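test_that("walk corpus has the contracted shape and obeys the transition law", {
  a <- manual_ajm(two_block_loa(c(2L, 1L), within = 1, across = 0))
  corpus <- sample_walks(a, walks_per_node = 10L, walk_length = 10L, seed = 1L)
  expect_identical(dim(corpus$walks), c(30L, 10L))
  expect_true(all(corpus$walks %in% 1:3))
  # 2-node graph: the only neighbor is the other node, so walks alternate
  b <- manual_ajm(two_block_loa(c(1L, 1L), across = 0.5))
  w2 <- sample_walks(b, seed = 3L)$walks
  expect_true(all(w2[, seq(1, 9, 2)] != w2[, seq(2, 10, 2)]))
  expect_true(all(w2[, 1:8] == w2[, 3:10]))
  # neighbors at LOA 0 and ln 3 -> step probabilities 1/4 and 3/4
  m <- matrix(0, 3, 3, dimnames = rep(list(sprintf("chr1:%d:A:G", 1:3)), 2))
  m[1, 2] <- m[2, 1] <- 0
  m[1, 3] <- m[3, 1] <- log(3)
  m[2, 3] <- m[3, 2] <- 0
  steps <- sample_walks(manual_ajm(m), walks_per_node = 2000L,
                        walk_length = 2L, seed = 5L)$walks
  first <- steps[steps[, 1] == 1L, 2L]
  expect_equal(mean(first == 3L), 0.75, tolerance = 0.035)
  # determinism
  expect_identical(sample_walks(a, seed = 11L), sample_walks(a, seed = 11L))
})

test_that("SkipGram separates disconnected cliques and is seed-deterministic", {
  a <- manual_ajm(two_block_loa(c(3L, 3L), within = 3, across = -6))
  corpus <- sample_walks(a, seed = 2L)
  tab <- embed_skipgram(corpus, seed = 2L)
  expect_identical(dim(tab$vectors), c(6L, 8L))
  expect_true(all(is.finite(tab$vectors)))
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  v <- tab$vectors
  within <- c(cosine(v[1, ], v[2, ]), cosine(v[2, ], v[3, ]),
              cosine(v[4, ], v[5, ]), cosine(v[5, ], v[6, ]))
  across <- c(cosine(v[1, ], v[4, ]), cosine(v[2, ], v[5, ]),
              cosine(v[3, ], v[6, ]))
  expect_gt(min(within), max(across))
  expect_identical(embed_skipgram(corpus, seed = 2L)$vectors, tab$vectors)
  # degenerate corpus of two alternating nodes still embeds every node
  b <- manual_ajm(two_block_loa(c(1L, 1L), across = 0))
  tab2 <- embed_skipgram(sample_walks(b, seed = 1L), seed = 1L)
  expect_identical(nrow(tab2$vectors), 2L)
  expect_true(all(is.finite(tab2$vectors)))
})

test_that("PCA embedding matches an eigendecomposition oracle on a fixed matrix", {
  m <- two_block_loa(c(3L, 3L), within = 1.5, across = -1.5)
  m[1, 2] <- m[2, 1] <- 1.2   # break exact symmetry between blocks
  a <- manual_ajm(m)
  tab <- embed_pca(a, dim = 2L)
  # oracle: centered data projected on covariance eigenvectors
  xc <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(m) - 1L), symmetric = TRUE)
  for (j in 1:2) {
    oracle <- xc %*% eig$vectors[, j]
    # compare up to the fixed sign convention
    expect_equal(abs(unname(tab$vectors[, j])), abs(c(oracle)),
                 tolerance = 1e-8)
  }
  # sign rule: largest-magnitude loading of each kept component is positive
  pr <- stats::prcomp(m, center = TRUE)
  for (j in 1:2) {
    load_j <- pr$rotation[, j] * (if (sign(pr$rotation[which.max(abs(pr$rotation[, j])), j]) < 0) -1 else 1)
    expect_gt(load_j[which.max(abs(load_j))], 0)
  }
  # first component separates the blocks
  expect_true(max(tab$vectors[1:3, 1]) < min(tab$vectors[4:6, 1]) ||
                min(tab$vectors[1:3, 1]) > max(tab$vectors[4:6, 1]))
  # variance ordering
  expect_gte(stats::var(tab$vectors[, 1]), stats::var(tab$vectors[, 2]))
})

test_that("PCA handles degenerate and undersized inputs by zero-padding", {
  z <- matrix(0, 3, 3, dimnames = rep(list(sprintf("chr1:%d:A:G", 1:3)), 2))
  tab <- NULL
  expect_warning(tab <- embed_pca(manual_ajm(z), dim = 2L), "padding")
  expect_identical(dim(tab$vectors), c(3L, 2L))
  expect_true(all(tab$vectors == 0))
  two <- manual_ajm(two_block_loa(c(1L, 1L), across = 1))
  tab2 <- NULL
  expect_warning(tab2 <- embed_pca(two, dim = 2L), "padding")
  expect_identical(dim(tab2$vectors), c(2L, 2L))
  expect_true(all(tab2$vectors[, 2] == 0))
})

test_that("PCA embedding is permutation-equivariant up to the sign rule", {
  m <- two_block_loa(c(3L, 4L), within = 2, across = -1)
  m[2, 5] <- m[5, 2] <- 0.7
  perm <- c(4L, 1L, 7L, 3L, 2L, 6L, 5L)
  tab <- embed_pca(manual_ajm(m), dim = 2L)
  tabp <- embed_pca(manual_ajm(m[perm, perm]), dim = 2L)
  expect_equal(tabp$vectors, tab$vectors[perm, ], tolerance = 1e-8)
})

test_that("NMF is nonnegative, near-exact on rank-1 input, and seed-deterministic", {
  for (s in 1:5) {
    x <- rand_cohort(10L, 5L, seed = s)
    w <- embed_nmf(build_ajm("G", x$variants, x), seed = s)$vectors
    expect_true(all(w >= 0))
    expect_true(all(is.finite(w)))
  }
  # all LOA equal -> AJNM is a rank-1-plus-diagonal-perturbation; at the
  # exact rank-1 matrix the reconstruction error vanishes at dim 1
  const <- matrix(log(2), 4, 4, dimnames = rep(list(sprintf("chr1:%d:A:G", 1:4)), 2))
  a <- manual_ajm(const)
  a$loa <- const          # keep nonzero diagonal so AJNM is exactly rank 1
  tab <- embed_nmf(a, dim = 1L, seed = 1L, max_iter = 2000L, tol = 1e-12)
  expect_lt(tab$params$rel_error, 1e-4)
  ref <- embed_nmf(a, dim = 1L, seed = 1L, max_iter = 2000L, tol = 1e-12)
  expect_identical(tab$vectors, ref$vectors)
})

test_that("NMF row space separates the blocks of a two-block matrix", {
  a <- manual_ajm(two_block_loa(c(3L, 3L), within = 2, across = -2))
  tab <- embed_nmf(a, dim = 2L, seed = 4L)
  cand <- cluster_embeddings(tab)
  expect_identical(attr(cand, "k"), 2L)
  got <- lapply(cand, `[[`, "variants")
  expect_true(setequal(got[[1]], a$variants[1:3]) ||
                setequal(got[[1]], a$variants[4:6]))
})
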