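APPROACHES <- c("lcw_sg", "gmf_nmf", "gmf_pca", "ctrl_gla", "ctrl_inv")

#' Pipeline configuration
#'
#' Collects every tunable of the discovery/evaluation pipeline with its
#' default: the train fraction and significance level, the LOA smoothing
#' constant, the walk and SkipGram hyperparameters of the LCW-SG backend,
#' the factorization rank of the GMF backends, and the clustering scan.
#'
#' @param seed master seed; per-gene and per-backend substreams are derived
#'   from it.
#' @param fraction training fraction for [split_cohort()].
#' @param alpha significance level for acceptance/reproduction (default 0.05).
#' @param epsilon LOA smoothing constant.
#' @param walks_per_node,walk_length random-walk corpus shape (defaults 10, 10).
#' @param sg_dim,sg_window,sg_epochs,sg_negative SkipGram hyperparameters.
#' @param gmf_dim factorization rank for PCA and NMF backends (default 2).
#' @param nmf_max_iter,nmf_tol NMF stopping rule.
#' @param k_min,k_max,linkage clustering scan range and linkage.
#' @return A list of class `vmn_config`.
#' @export
vmn_config <- function(seed = 1L, fraction = 0.5, alpha = 0.05,
                       epsilon = 1e-3, walks_per_node = 10L,
                       walk_length = 10L, sg_dim = 8L, sg_window = 5L,
                       sg_epochs = 5L, sg_negative = 5L, gmf_dim = 2L,
                       nmf_max_iter = 200L, nmf_tol = 1e-4, k_min = 2L,
                       k_max = 20L, linkage = "ward") {
  structure(list(seed = as.integer(seed), fraction = fraction, alpha = alpha,
                 epsilon = epsilon, walks_per_node = walks_per_node,
                 walk_length = walk_length, sg_dim = sg_dim,
                 sg_window = sg_window, sg_epochs = sg_epochs,
                 sg_negative = sg_negative, gmf_dim = gmf_dim,
                 nmf_max_iter = nmf_max_iter, nmf_tol = nmf_tol,
                 k_min = k_min, k_max = k_max, linkage = linkage),
            class = "vmn_config")
}

embed_gene <- function(approach, ajm, config, gene_seed) {
  switch(approach,
    lcw_sg = {
      corpus <- sample_walks(ajm, config$walks_per_node, config$walk_length,
                             seed = gene_seed)
      embed_skipgram(corpus, dim = config$sg_dim, window = config$sg_window,
                     epochs = config$sg_epochs, seed = gene_seed,
                     negative = config$sg_negative)
    },
    gmf_pca = embed_pca(ajm, dim = config$gmf_dim),
    gmf_nmf = embed_nmf(ajm, dim = config$gmf_dim, seed = gene_seed,
                        max_iter = config$nmf_max_iter, tol = config$nmf_tol),
    stop_("unknown embedding backend '%s'", approach))
}

#' Discover module candidates with one approach
#'
#' For the representation-learning approaches each gene's association matrix
#' is built from the training cohort, embedded with the requested backend,
#' and clustered; genes with a single observed variant cannot form a network
#' and contribute one whole-gene candidate instead, keeping candidate counts
#' comparable across approaches. The control approaches need no learning and
#' read the gene map directly. Only the training split may be passed here —
#' module discovery must never see test data.
#'
#' @param approach one of `"lcw_sg"`, `"gmf_nmf"`, `"gmf_pca"`,
#'   `"ctrl_gla"`, `"ctrl_inv"`.
#' @param train training [cohort] with phenotype.
#' @param map a [gene_map] (typically already restricted to train-observed
#'   variants via [restrict_to_observed()]).
#' @param config a [vmn_config].
#' @return A list of `module_candidate` objects.
#' @export
run_approach <- function(approach, train, map, config = vmn_config()) {
  approach <- match.arg(approach, APPROACHES)
  if (approach == "ctrl_gla") return(modules_gla(map))
  if (approach == "ctrl_inv") return(modules_inv(map))
  a_idx <- match(approach, APPROACHES)
  out <- list()
  for (i in seq_along(map)) {
    g <- names(map)[i]
    vars <- map[[g]]
    if (length(vars) < 2L) {
      cand <- list(new_module_candidate(g, vars, approach, 1L))
    } else {
      gene_seed <- derive_seed(config$seed, a_idx * 100000L + i)
      ajm <- build_ajm(g, vars, train, epsilon = config$epsilon)
      tab <- embed_gene(approach, ajm, config, gene_seed)
      cand <- cluster_embeddings(tab, k_min = config$k_min,
                                 k_max = config$k_max,
                                 linkage = config$linkage)
    }
    out <- c(out, cand)
  }
  out
}

#' Approach result from raw counts
#'
#' The acceptance rate is accepted/candidates and the reproduction rate is
#' reproduced/accepted, both kept as unrounded ratios of the raw counts;
#' zero denominators yield `NA` ("undefined"), never a silent 0.
#'
#' @param approach approach label.
#' @param n_candidates number of module candidates.
#' @param n_accepted_train candidates significant on the training split.
#' @param n_reproduced_test accepted candidates still significant on test.
#' @param alpha significance level the counts were produced with.
#' @return An object of class `approach_result`.
#' @export
approach_result <- function(approach, n_candidates, n_accepted_train,
                            n_reproduced_test, alpha = 0.05) {
  if (n_accepted_train > n_candidates || n_reproduced_test > n_accepted_train) {
    stop_("inconsistent counts: reproduced <= accepted <= candidates required")
  }
  structure(list(
    approach = approach,
    n_candidates = as.numeric(n_candidates),
    n_accepted_train = as.numeric(n_accepted_train),
    acceptance_rate = if (n_candidates > 0) n_accepted_train / n_candidates else NA_real_,
    n_reproduced_test = as.numeric(n_reproduced_test),
    reproduction_rate = if (n_accepted_train > 0) n_reproduced_test / n_accepted_train else NA_real_,
    alpha = alpha),
    class = "approach_result")
}

#' @export
print.approach_result <- function(x, ...) {
  cat(sprintf("<approach_result> %s: %s candidates, %s accepted (%s), %s reproduced (%s)\n",
              x$approach, format(x$n_candidates), format(x$n_accepted_train),
              format_rate(x$acceptance_rate), format(x$n_reproduced_test),
              format_rate(x$reproduction_rate)))
  invisible(x)
}

format_rate <- function(r) {
  if (is.na(r)) "undefined" else sprintf("%.4f", r)
}

#' Train/test acceptance and reproduction of module candidates
#'
#' The reproducibility protocol: (1) score every candidate on the training
#' split and accept those with FEP below `alpha`; (2) re-score the accepted
#' candidates on the held-out split and count how many stay below `alpha`.
#' The acceptance rate is accepted/candidates; the reproduction rate is
#' reproduced/accepted. Activation thresholds are recomputed within each
#' split being scored.
#'
#' @param candidates list of `module_candidate` objects discovered on the
#'   training split only.
#' @param train,test the two [cohort] splits.
#' @param alpha significance level (default 0.05).
#' @param approach label recorded on the result (defaults to the candidates'
#'   approach).
#' @return An `approach_result`.
#' @export
acceptance_and_reproduction <- function(candidates, train, test,
                                        alpha = 0.05, approach = NULL) {
  approach <- approach %||%
    (if (length(candidates)) candidates[[1L]]$approach else "none")
  n <- length(candidates)
  fep_train <- vapply(candidates, function(m) fep(contingency(m, train)),
                      numeric(1L))
  accepted <- which(fep_train < alpha)
  fep_test <- vapply(candidates[accepted],
                     function(m) fep(contingency(m, test)), numeric(1L))
  approach_result(approach, n, length(accepted), sum(fep_test < alpha),
                  alpha)
}

#' Ratio of two reproduction rates
#'
#' Computed from the raw counts (unrounded rates), since presentation-level
#' rounding loses the precision the comparison needs.
#'
#' @param r1,r2 `approach_result` objects with defined reproduction rates.
#' @return `r1`'s reproduction rate over `r2`'s.
#' @export
rate_ratio <- function(r1, r2) {
  if (is.na(r1$reproduction_rate) || is.na(r2$reproduction_rate)) {
    stop_("reproduction rate undefined; cannot form a ratio")
  }
  r1$reproduction_rate / r2$reproduction_rate
}

#' Run the full reproducibility benchmark
#'
#' Splits the cohort once (stratified by phenotype), restricts the gene map
#' to variants observed in the training split, discovers module candidates
#' with all five approaches on the training split, and measures acceptance
#' and reproduction for each. All approaches share the same split.
#'
#' @param x a [cohort] with phenotype.
#' @param map a [gene_map].
#' @param config a [vmn_config].
#' @return An object of class `eval_report`: `$results` is a named list of
#'   `approach_result`s in fixed order (lcw_sg, gmf_nmf, gmf_pca, ctrl_gla,
#'   ctrl_inv); `$provenance` records the configuration and package version.
#' @export
evaluate_all <- function(x, map, config = vmn_config()) {
  splits <- split_cohort(x, fraction = config$fraction, seed = config$seed)
  map_train <- suppressMessages(restrict_to_observed(splits$train, map))
  results <- lapply(APPROACHES, function(a) {
    cand <- run_approach(a, splits$train, map_train, config)
    acceptance_and_reproduction(cand, splits$train, splits$test,
                                alpha = config$alpha, approach = a)
  })
  names(results) <- APPROACHES
  structure(list(
    results = results,
    provenance = c(unclass(config),
                   list(n_patients = length(x$patients),
                        n_genes = length(map_train),
                        package_version =
                          as.character(utils::packageVersion("varmodnet"))))),
    class = "eval_report")
}

#' Tabulate an evaluation report
#'
#' @param report an `eval_report`.
#' @return A data.frame with one row per approach: approach, n_candidates,
#'   n_accepted_train, acceptance_rate, n_reproduced_test, reproduction_rate
#'   (rates rounded to 4 decimals for presentation).
#' @export
report_table <- function(report) {
  rows <- lapply(report$results, function(r) {
    data.frame(approach = r$approach, n_candidates = r$n_candidates,
               n_accepted_train = r$n_accepted_train,
               acceptance_rate = round(r$acceptance_rate, 4L),
               n_reproduced_test = r$n_reproduced_test,
               reproduction_rate = round(r$reproduction_rate, 4L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(report_table(x))
  invisible(x)
}

#' Write an evaluation report (TSV table + JSON with provenance)
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed); writes `report.tsv` and
#'   `report.json`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report_table(report), file.path(dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(results = lapply(report$results, unclass),
         provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
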