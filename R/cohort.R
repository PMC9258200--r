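#' Cohort objects
#'
#' A cohort bundles a binary patient-by-variant carrier matrix with an
#' optional binary phenotype vector (1 = case, e.g. early-onset; 0 = control).
#' Carrier status is presence/absence: a patient either carries a variant
#' (at least one alternate allele) or does not; zygosity is not retained.
#'
#' @param carriers integer/numeric matrix with values in \{0, 1\}; rows are
#'   patients, columns are variants; both must carry unique dimnames.
#' @param phenotype optional vector in \{0, 1\}, one value per patient, named
#'   or in row order.
#' @return An object of class `cohort`: a list with elements `patients`,
#'   `variants`, `carriers` (integer matrix) and `phenotype` (integer vector
#'   or `NULL`).
#' @export
cohort <- function(carriers, phenotype = NULL) {
  if (!is.matrix(carriers)) stop_("'carriers' must be a matrix")
  if (is.null(rownames(carriers)) || is.null(colnames(carriers))) {
    stop_("'carriers' must have patient rownames and variant colnames")
  }
  if (anyDuplicated(rownames(carriers))) {
    stop_("duplicate patient id(s): %s",
          paste(unique(rownames(carriers)[duplicated(rownames(carriers))]),
                collapse = ", "))
  }
  if (anyDuplicated(colnames(carriers))) {
    stop_("duplicate variant id(s): %s",
          paste(unique(colnames(carriers)[duplicated(colnames(carriers))]),
                collapse = ", "))
  }
  storage.mode(carriers) <- "integer"
  if (any(is.na(carriers)) || !all(carriers %in% c(0L, 1L))) {
    stop_("carrier matrix entries must all be 0 or 1")
  }
  obj <- structure(
    list(patients = rownames(carriers), variants = colnames(carriers),
         carriers = carriers, phenotype = NULL),
    class = "cohort")
  if (!is.null(phenotype)) obj <- set_phenotype(obj, phenotype)
  obj
}

set_phenotype <- function(x, phenotype) {
  if (!is.null(names(phenotype))) {
    missing <- setdiff(x$patients, names(phenotype))
    if (length(missing)) {
      stop_("phenotype missing for patient(s): %s",
            paste(missing, collapse = ", "))
    }
    phenotype <- phenotype[x$patients]
  } else if (length(phenotype) != length(x$patients)) {
    stop_("phenotype length (%d) != number of patients (%d)",
          length(phenotype), length(x$patients))
  }
  phenotype <- as.integer(phenotype)
  if (any(is.na(phenotype)) || !all(phenotype %in% c(0L, 1L))) {
    stop_("phenotype values must all be 0 or 1")
  }
  names(phenotype) <- x$patients
  x$phenotype <- phenotype
  x
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d patients x %d variants", length(x$patients),
              length(x$variants)))
  if (!is.null(x$phenotype)) {
    cat(sprintf("; phenotype: %d cases / %d controls",
                sum(x$phenotype == 1L), sum(x$phenotype == 0L)))
  } else {
    cat("; phenotype: <none>")
  }
  cat("\n")
  invisible(x)
}

n_patients <- function(x) length(x$patients)

subset_cohort <- function(x, idx) {
  out <- x
  out$carriers <- x$carriers[idx, , drop = FALSE]
  out$patients <- rownames(out$carriers)
  if (!is.null(x$phenotype)) out$phenotype <- x$phenotype[idx]
  out
}

#' Read a patient-by-variant carrier matrix
#'
#' TSV dialect: tab-delimited, UTF-8, a header row of variant ids
#' ("chrom:pos:ref:alt"), first column the patient id, remaining cells 0/1.
#' VCF dialect (requires the vcfR package): every sample genotype containing
#' at least one alternate allele becomes carrier = 1; missing genotypes
#' (`./.` and friends) become 0, and variant ids are assembled as
#' "chrom:pos:ref:alt".
#'
#' @param path file to read.
#' @param format `"tsv"` or `"vcf"`.
#' @return A [cohort] without phenotype.
#' @export
read_carrier_matrix <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_("no such file: %s", path)
  if (format == "tsv") read_carrier_tsv(path) else read_carrier_vcf(path)
}

read_carrier_tsv <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L) stop_("carrier TSV needs a patient column plus >=1 variant column")
  patients <- raw[[1L]]
  variants <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  bad <- which(matrix(!(cells %in% c("0", "1")), nrow(cells)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_("malformed carrier cell '%s' at patient '%s', variant '%s'",
          cells[bad[1L, , drop = FALSE]], patients[bad[1L, 1L]],
          variants[bad[1L, 2L]])
  }
  m <- matrix(as.integer(cells), nrow = nrow(cells),
              dimnames = list(patients, variants))
  cohort(m)
}

read_carrier_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
               sep = ":")
  gt <- vcfR::extract.gt(v, element = "GT")
  # carrier iff any allele index in GT is a non-zero digit; NA / "./." -> 0
  carrier <- !is.na(gt) & grepl("[1-9]", gt)
  m <- t(matrix(as.integer(carrier), nrow = nrow(gt),
                dimnames = list(ids, colnames(gt))))
  cohort(m)
}

#' Attach a phenotype table to a cohort
#'
#' @param x a [cohort].
#' @param phenotype_table path to a two-column TSV (patient id, 0/1); a header
#'   line is tolerated and skipped.
#' @return The cohort with `phenotype` aligned to its patient order.
#' @export
attach_phenotype <- function(x, phenotype_table) {
  if (!file.exists(phenotype_table)) stop_("no such file: %s", phenotype_table)
  tab <- utils::read.delim(phenotype_table, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) != 2L) stop_("phenotype table must have exactly 2 columns")
  if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab[1L, 2L])))) {
    tab <- tab[-1L, , drop = FALSE]   # header line
  }
  if (anyDuplicated(tab[[1L]])) {
    stop_("duplicate patient id(s) in phenotype table")
  }
  bad <- !(tab[[2L]] %in% c("0", "1"))
  if (any(bad)) {
    stop_("phenotype value '%s' for patient '%s' is not 0/1",
          tab[[2L]][bad][1L], tab[[1L]][bad][1L])
  }
  ph <- stats::setNames(as.integer(tab[[2L]]), tab[[1L]])
  set_phenotype(x, ph)
}

#' Stratified train/test split of a cohort
#'
#' Within each phenotype class, `floor(fraction * n_class)` patients are drawn
#' at random into the training split; the remainder go to the test split, so
#' an odd class count puts the extra patient in test. The split is
#' deterministic given `seed`.
#'
#' @param x a [cohort] with phenotype.
#' @param fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return `list(train = cohort, test = cohort)`.
#' @export
split_cohort <- function(x, fraction = 0.5, seed = 1L) {
  if (is.null(x$phenotype)) stop_("cohort has no phenotype; cannot stratify")
  if (!(fraction > 0 && fraction < 1)) stop_("'fraction' must be in (0, 1)")
  counts <- table(factor(x$phenotype, levels = c(0L, 1L)))
  if (any(counts < 2L)) {
    stop_("each phenotype class needs >=2 patients (have %s)",
          paste(counts, collapse = "/"))
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(c(0L, 1L), function(k) {
      idx <- which(x$phenotype == k)
      sort(sample(idx, floor(fraction * length(idx))))
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = subset_cohort(x, train_idx),
       test = subset_cohort(x, setdiff(seq_along(x$patients), train_idx)))
}

#' Gene map: gene -> ordered variants
#'
#' @param x a named list mapping gene id to a character vector of variant ids.
#' @return An object of class `gene_map`.
#' @export
gene_map <- function(x) {
  if (!is.list(x)) stop_("gene map must be a named list gene -> variant ids")
  if (length(x) == 0L) {
    return(structure(stats::setNames(list(), character()), class = "gene_map"))
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop_("gene map must be a named list gene -> variant ids")
  }
  if (anyDuplicated(names(x))) stop_("duplicate gene id(s) in gene map")
  x <- lapply(x, as.character)
  if (any(lengths(x) == 0L)) {
    stop_("gene(s) with empty variant list: %s",
          paste(names(x)[lengths(x) == 0L], collapse = ", "))
  }
  all_vars <- unlist(x, use.names = FALSE)
  if (anyDuplicated(all_vars)) {
    stop_("variant(s) assigned to more than one gene: %s",
          paste(unique(all_vars[duplicated(all_vars)]), collapse = ", "))
  }
  structure(x, class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  cat(sprintf("<gene_map> %d genes, %d variants\n", length(x),
              sum(lengths(x))))
  invisible(x)
}

#' @export
`[.gene_map` <- function(x, i) {
  structure(NextMethod(), class = "gene_map")
}

#' Read / write a two-column variant-to-gene TSV
#'
#' Columns: variant_id, gene_id (with header). Genes keep the order in which
#' they first appear; variants keep file order within each gene.
#'
#' @param path file path.
#' @return [read_gene_map()] returns a [gene_map].
#' @export
read_gene_map <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "")
  if (ncol(tab) != 2L) stop_("gene map TSV must have 2 columns")
  genes <- unique(tab[[2L]])
  gene_map(stats::setNames(
    lapply(genes, function(g) tab[[1L]][tab[[2L]] == g]), genes))
}

#' @rdname read_gene_map
#' @param map a [gene_map].
#' @export
write_gene_map <- function(map, path) {
  df <- data.frame(variant_id = unlist(map, use.names = FALSE),
                   gene_id = rep(names(map), lengths(map)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cohort artifacts as TSV
#'
#' @param x a [cohort].
#' @param path output file.
#' @export
write_carrier_matrix <- function(x, path) {
  df <- data.frame(patient_id = x$patients, x$carriers,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_carrier_matrix
#' @export
write_phenotype <- function(x, path) {
  if (is.null(x$phenotype)) stop_("cohort has no phenotype to write")
  df <- data.frame(patient_id = x$patients, phenotype = x$phenotype)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop variants unobserved in a cohort from a gene map
#'
#' Variants carried by zero patients of `x` are removed from every gene, and
#' genes left with no observed variant are dropped entirely (mirroring
#' missing-in-split bookkeeping when module discovery runs on a training
#' split). The operation is idempotent.
#'
#' @param x a [cohort].
#' @param map a [gene_map].
#' @return A [gene_map] restricted to variants observed in `x`.
#' @export
restrict_to_observed <- function(x, map) {
  observed <- x$variants[colSums(x$carriers) > 0L]
  trimmed <- lapply(map, function(v) v[v %in% observed])
  n_dropped_var <- sum(lengths(map)) - sum(lengths(trimmed))
  keep <- lengths(trimmed) > 0L
  if (n_dropped_var > 0L || any(!keep)) {
    message(sprintf("restrict_to_observed: dropped %d unobserved variant(s) and %d empty gene(s)",
                    n_dropped_var, sum(!keep)))
  }
  gene_map(trimmed[keep])
}
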