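mk_module <- function(variants, gene = "G", approach = "gmf_pca", id = "m1") {
  structure(list(module_id = id, gene_id = gene, approach = approach,
                 variants = variants),
            class = "module_candidate")
}

test_that("activation level, threshold and status follow their definitions", {
  x <- toy_cohort()
  m <- mk_module(x$variants)          # all four variants
  expect_equal(mal("P1", m, x), 0.5)  # P1 carries 2 of 4
  expect_equal(mal("P8", m, x), 0)
  expect_equal(mal("P2", m, x), 0.75)
  mals <- vapply(x$patients, function(p) mal(p, m, x), numeric(1))
  expect_equal(activation_threshold(m, x), mean(mals))
  thr <- activation_threshold(m, x)
  expect_identical(mas("P2", m, x, thr), 1L)
  expect_identical(mas("P8", m, x, thr), 0L)
  # strictness: equal MAL never activates
  expect_identical(mas("P1", m, x, 0.5), 0L)
  # all patients identical -> nobody strictly exceeds the mean
  u <- cohort(matrix(1L, 4, 2, dimnames = list(sprintf("P%d", 1:4),
                                               c("a:1:A:G", "b:1:A:G"))),
              c(1L, 1L, 0L, 0L))
  mu <- mk_module(u$variants)
  ct <- contingency(mu, u)
  expect_identical(ct$a + ct$b, 0L)
})

test_that("contingency tallies activation by phenotype and is permutation-invariant", {
  x <- toy_cohort()
  m <- mk_module("chr1:100:A:G", approach = "ctrl_inv")
  ct <- contingency(m, x)
  # carrier column is the activation for single-variant controls
  expect_identical(c(ct$a, ct$b, ct$c, ct$d), c(3L, 1L, 1L, 3L))
  expect_identical(ct$a + ct$b + ct$c + ct$d, 8L)
  perm <- c(5L, 2L, 8L, 1L, 3L, 7L, 4L, 6L)
  xp <- cohort(x$carriers[perm, ], x$phenotype[perm])
  expect_identical(contingency(m, xp), ct)
})

test_that("the one-sided exact p-value matches enumeration, closed forms and fisher.test", {
  expect_equal(fep(c(a = 5, b = 1, c = 1, d = 5)), 37 / 924, tolerance = 1e-12)
  expect_gt(fep(c(a = 1, b = 1, c = 1, d = 1)), 0.5)
  # maximal a given margins -> point mass of the most extreme table
  expect_equal(fep(c(a = 4, b = 0, c = 0, d = 4)), 1 / choose(8, 4),
               tolerance = 1e-12)
  # exhaustive enumeration oracle for all tables with total <= 24
  for (n_tot in c(6L, 12L, 18L, 24L)) {
    combos <- expand.grid(a = 0:n_tot, b = 0:n_tot, c = 0:n_tot)
    combos <- combos[rowSums(combos) <= n_tot, ]
    combos$d <- n_tot - rowSums(combos)
    idx <- seq_len(nrow(combos))
    got <- fep(list(a = combos$a, b = combos$b, c = combos$c, d = combos$d))
    want <- mapply(oracle_fep, combos$a, combos$b, combos$c, combos$d)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # spot-check agreement with the standard exact-test implementation
  set.seed(3)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 8), 2, 2)
    expect_equal(fep(c(a = tb[1, 1], b = tb[1, 2], c = tb[2, 1], d = tb[2, 2])),
                 stats::fisher.test(tb, alternative = "greater")$p.value,
                 tolerance = 1e-9)
  }
})

test_that("shifting a count from inactivated-case to activated-case never raises the p-value", {
  set.seed(4)
  for (i in 1:20) {
    a <- sample(0:10, 1); b <- sample(0:10, 1)
    c <- sample(1:10, 1); d <- sample(0:10, 1)
    expect_lte(fep(c(a = a + 1, b = b, c = c - 1, d = d)),
               fep(c(a = a, b = b, c = c, d = d)) + 1e-12)
  }
})

test_that("the odds ratio follows the cell formula with honest zero handling", {
  expect_identical(fer(c(a = 20, b = 10, c = 10, d = 20)), 4)
  expect_identical(fer(c(a = 1, b = 1, c = 1, d = 1)), 1)
  expect_identical(fer(c(a = 5, b = 0, c = 1, d = 5)), Inf)
  expect_true(is.nan(fer(c(a = 0, b = 0, c = 5, d = 0))))
  expect_identical(fer(c(a = 0, b = 2, c = 3, d = 4)), 0)
  expect_equal(fer(c(a = 5, b = 0, c = 1, d = 5), correction = TRUE),
               (5.5 * 5.5) / (0.5 * 1.5), tolerance = 1e-12)
  # swapping the phenotype columns inverts the ratio when all cells > 0
  set.seed(5)
  for (i in 1:10) {
    ct <- c(a = sample(1:20, 1), b = sample(1:20, 1),
            c = sample(1:20, 1), d = sample(1:20, 1))
    swapped <- c(a = ct[["b"]], b = ct[["a"]], c = ct[["d"]], d = ct[["c"]])
    expect_equal(fer(ct) * fer(swapped), 1, tolerance = 1e-12)
  }
})

test_that("score_module bundles threshold, counts and statistics coherently", {
  x <- toy_cohort()
  s <- score_module(mk_module(x$variants[1:2], id = "G/m/01"), x)
  ct <- s$contingency
  expect_identical(ct$a + ct$b + ct$c + ct$d, 8L)
  expect_equal(s$fep, fep(ct))
  expect_equal(s$fer, fer(ct))
  expect_false(is.na(s$thr))
  # single-variant control: contingency equals the carrier-vs-phenotype table
  sv <- score_module(mk_module("chr1:100:A:G", approach = "ctrl_inv"), x)
  expect_identical(c(sv$contingency$a, sv$contingency$b),
                   c(3L, 1L))
  expect_true(is.na(sv$thr))
})

test_that("null modules score near FER 1 and planted strong modules reach significance", {
  # aggregate over many null modules: no systematic enrichment
  cfg <- sim_config_null(n_patients = 2000L, n_genes = 12L, seed = 31L)
  sim <- simulate_cohort(cfg)
  cands <- modules_gla(sim_gene_map(cfg))
  scores <- score_modules(cands, sim$cohort)
  expect_gt(median(scores$fep), 0.2)
  finite_fer <- scores$fer[is.finite(scores$fer) & scores$fer > 0]
  expect_lt(abs(median(log(finite_fer))), 0.5)
  # planted strong modules are detected across seeds
  hits <- vapply(1:5, function(s) {
    sim <- simulate_cohort(sim_config_strong(seed = s))
    tl <- truth_labels(sim$truth, "GENE01")
    all(vapply(1:2, function(i) {
      fep(contingency(mk_module(names(tl)[tl == i]), sim$cohort)) < 0.05
    }, logical(1L)))
  }, logical(1L))
  expect_gte(mean(hits), 0.8)
})
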