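test_that("carrier matrix, phenotype and gene map survive a write/read round trip", {
  x <- toy_cohort()
  map <- gene_map(list(GENE1 = x$variants[1:2], GENE2 = x$variants[3:4]))
  d <- withr::local_tempdir()
  write_carrier_matrix(x, file.path(d, "c.tsv"))
  write_phenotype(x, file.path(d, "p.tsv"))
  write_gene_map(map, file.path(d, "g.tsv"))
  y <- read_carrier_matrix(file.path(d, "c.tsv"), format = "tsv")
  y <- attach_phenotype(y, file.path(d, "p.tsv"))
  expect_identical(y$carriers, x$carriers)
  expect_identical(y$phenotype, x$phenotype)
  expect_identical(read_gene_map(file.path(d, "g.tsv")), map)
})

test_that("malformed carrier cells and duplicate ids are rejected with context", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.tsv")
  writeLines(c("patient_id\tchr1:1:A:G\tchr1:2:C:T",
               "P1\t1\t0", "P2\t0\t2"), f)
  expect_error(read_carrier_matrix(f), "P2.*chr1:2:C:T")
  writeLines(c("patient_id\tchr1:1:A:G\tchr1:1:A:G",
               "P1\t1\t0"), f)
  expect_error(read_carrier_matrix(f), "duplicate variant")
  writeLines(c("patient_id\tchr1:1:A:G", "P1\t1", "P1\t0"), f)
  expect_error(read_carrier_matrix(f), "duplicate patient")
})

test_that("VCF genotypes collapse to zygosity-blind carrier status", {
  skip_if_not_installed("vcfR")
  d <- withr::local_tempdir()
  f <- file.path(d, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tP1\tP2",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t0/0",
    "chr1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t1/1\t./.",
    "chr2\t300\t.\tG\tA\t.\tPASS\t.\tGT\t0|0\t0/1"), f)
  x <- read_carrier_matrix(f, format = "vcf")
  expect_identical(x$variants, c("chr1:100:A:G", "chr1:200:C:T", "chr2:300:G:A"))
  expect_identical(unname(x$carriers["P1", ]), c(1L, 1L, 0L))   # het and hom-alt both carry
  expect_identical(unname(x$carriers["P2", ]), c(0L, 0L, 1L))   # missing genotype -> 0
})

test_that("phenotype attachment validates completeness and values", {
  x <- toy_cohort()
  x$phenotype <- NULL
  d <- withr::local_tempdir()
  f <- file.path(d, "p.tsv")
  writeLines(c("P1\t1", "P3\t0"), f)
  expect_error(attach_phenotype(x, f), "P2")
  writeLines(paste(x$patients, c(2, rep(0, 7)), sep = "\t"), f)
  expect_error(attach_phenotype(x, f), "not 0/1")
  writeLines(paste(rev(x$patients), rep(c(0, 1), 4), sep = "\t"), f)
  y <- attach_phenotype(x, f)
  expect_identical(names(y$phenotype), x$patients)  # aligned to cohort order
})

test_that("split is stratified, exhaustive, disjoint and seed-deterministic", {
  set.seed(5)
  m <- matrix(rbinom(20 * 3, 1, 0.4), 20, 3,
              dimnames = list(sprintf("P%02d", 1:20),
                              sprintf("chr1:%d:A:G", 1:3)))
  x <- cohort(m, phenotype = rep(c(1L, 0L), c(4L, 16L)))
  sp <- split_cohort(x, fraction = 0.5, seed = 42)
  expect_identical(sum(sp$train$phenotype), 2L)
  expect_identical(length(sp$train$patients), 10L)
  expect_setequal(c(sp$train$patients, sp$test$patients), x$patients)
  expect_length(intersect(sp$train$patients, sp$test$patients), 0L)
  sp2 <- split_cohort(x, fraction = 0.5, seed = 42)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_cohort(x, fraction = 0.5, seed = 43)))
})

test_that("odd class counts put the remainder patient in the test split", {
  # same arithmetic as a 3,181 / 29,978 case-control cohort at fraction 0.5:
  # floor() to train, remainder to test
  n_case <- 3181L; n_ctrl <- 29978L
  m <- matrix(1L, n_case + n_ctrl, 1,
              dimnames = list(sprintf("P%05d", seq_len(n_case + n_ctrl)),
                              "chr1:1:A:G"))
  x <- cohort(m, phenotype = rep(c(1L, 0L), c(n_case, n_ctrl)))
  sp <- split_cohort(x, fraction = 0.5, seed = 1)
  expect_identical(sum(sp$train$phenotype == 1L), 1590L)
  expect_identical(sum(sp$test$phenotype == 1L), 1591L)
  expect_identical(sum(sp$train$phenotype == 0L), 14989L)
  expect_identical(sum(sp$test$phenotype == 0L), 14989L)
})

test_that("restrict_to_observed drops uncarried variants and empty genes, idempotently", {
  m <- matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L), 3, 3,
              dimnames = list(c("P1", "P2", "P3"),
                              c("chr1:1:A:G", "chr1:2:C:T", "chr2:1:G:A")))
  x <- cohort(m, phenotype = c(1L, 0L, 0L))
  map <- gene_map(list(G1 = c("chr1:1:A:G", "chr1:2:C:T"), G2 = "chr2:1:G:A"))
  expect_message(obs <- restrict_to_observed(x, map), "1 unobserved.*1 empty")
  expect_identical(names(obs), "G1")
  expect_identical(obs$G1, c("chr1:1:A:G", "chr1:2:C:T"))
  expect_identical(suppressMessages(restrict_to_observed(x, obs)), obs)
  # all-observed map passes through unchanged
  full <- gene_map(list(G1 = c("chr1:1:A:G", "chr1:2:C:T")))
  expect_identical(suppressMessages(restrict_to_observed(x, full)), full)
})

test_that("gene map validation rejects shared variants and empty genes", {
  expect_error(gene_map(list(G1 = "v1", G2 = "v1")), "more than one gene")
  expect_error(gene_map(list(G1 = character())), "empty variant list")
  expect_length(gene_map(list()), 0L)
})
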