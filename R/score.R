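#' Module activation level of a patient
#'
#' The fraction of the module's variants the patient carries.
#'
#' @param patient patient id.
#' @param module a `module_candidate`.
#' @param x a [cohort].
#' @return A value in `[0, 1]`.
#' @export
mal <- function(patient, module, x) {
  if (!length(module$variants)) stop_("module '%s' is empty", module$module_id)
  mean(x$carriers[patient, module$variants])
}

# MAL for every patient at once.
mal_all <- function(module, x) {
  if (!length(module$variants)) stop_("module '%s' is empty", module$module_id)
  rowMeans(x$carriers[, module$variants, drop = FALSE])
}

#' Activation threshold of a module
#'
#' The mean activation level over all patients of the cohort being scored.
#' When train and test splits are scored separately, each split uses its own
#' mean.
#'
#' @inheritParams mal
#' @return The cohort-mean activation level.
#' @export
activation_threshold <- function(module, x) {
  mean(mal_all(module, x))
}

#' Module activation status of a patient
#'
#' Activated (1) iff the activation level strictly exceeds the threshold.
#' The strict inequality means that when every patient has the same
#' activation level, no patient is activated.
#'
#' @inheritParams mal
#' @param thr_value threshold, typically from [activation_threshold()].
#' @return 0 or 1.
#' @export
mas <- function(patient, module, x, thr_value) {
  as.integer(mal(patient, module, x) > thr_value)
}

new_contingency <- function(a, b, c, d) {
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c),
                 d = as.integer(d)),
            class = "module_contingency")
}

#' @export
print.module_contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2L, 2L,
              dimnames = list(c("activated", "inactivated"),
                              c("case", "control")))
  print(m)
  invisible(x)
}

# Activation status for every patient: carrier status itself for
# single-variant control candidates, thresholded activation level otherwise.
activation_vector <- function(module, x) {
  if (identical(module$approach, "ctrl_inv")) {
    as.integer(x$carriers[, module$variants[1L]])
  } else {
    m <- mal_all(module, x)
    as.integer(m > mean(m))
  }
}

#' Activation-by-phenotype contingency table of a module
#'
#' Cross-tabulates activation status against phenotype over all patients:
#' `a` = activated cases, `b` = activated controls, `c` = inactivated cases,
#' `d` = inactivated controls; `a + b + c + d` equals the cohort size.
#'
#' @inheritParams mal
#' @return A `module_contingency`.
#' @export
contingency <- function(module, x) {
  if (is.null(x$phenotype)) stop_("cohort has no phenotype")
  act <- activation_vector(module, x)
  case <- x$phenotype == 1L
  new_contingency(sum(act == 1L & case), sum(act == 1L & !case),
                  sum(act == 0L & case), sum(act == 0L & !case))
}

#' One-sided Fisher's exact p-value (positive direction)
#'
#' Upper-tail hypergeometric probability `P(X >= a)` with all margins fixed:
#' the significance of a *positive* correlation between module activation
#' and the case phenotype. Smaller values mean stronger positive association;
#' depletion is never flagged.
#'
#' @param ct a `module_contingency`, or a vector/list with elements
#'   `a, b, c, d`.
#' @return A p-value in `[0, 1]`.
#' @export
fep <- function(ct) {
  ct <- as_counts(ct)
  stats::phyper(ct$a - 1L, ct$a + ct$c, ct$b + ct$d, ct$a + ct$b,
                lower.tail = FALSE)
}

#' Prior odds ratio of the activation-by-phenotype table
#'
#' `(a/b) / (c/d)`, evaluated as `(a d) / (b c)`. With a zero in the
#' denominator product the ratio is reported honestly: `Inf` when `a d > 0`,
#' and `NaN` ("undefined") when both products are zero. An optional
#' Haldane–Anscombe correction adds 0.5 to every cell first.
#'
#' @inheritParams fep
#' @param correction apply the +0.5 continuity correction (default `FALSE`).
#' @return A nonnegative number, `Inf`, or `NaN`.
#' @export
fer <- function(ct, correction = FALSE) {
  ct <- as_counts(ct)
  a <- ct$a; b <- ct$b; c <- ct$c; d <- ct$d
  if (correction) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  num <- a * d
  den <- b * c
  if (den > 0) num / den else if (num > 0) Inf else NaN
}

as_counts <- function(ct) {
  if (inherits(ct, "module_contingency")) return(ct)
  ct <- as.list(ct)
  if (is.null(names(ct)) || !all(c("a", "b", "c", "d") %in% names(ct))) {
    names(ct) <- c("a", "b", "c", "d")
  }
  ct
}

#' Score a module candidate against a cohort
#'
#' Bundles the activation threshold (recomputed on the cohort being scored),
#' per-patient activation, the contingency table, the one-sided exact
#' p-value and the odds ratio. Single-variant control candidates
#' (`approach == "ctrl_inv"`) are scored on carrier status directly, with no
#' threshold.
#'
#' @inheritParams mal
#' @param fer_correction passed to [fer()].
#' @return An object of class `module_score`.
#' @export
score_module <- function(module, x, fer_correction = FALSE) {
  ct <- contingency(module, x)
  thr <- if (identical(module$approach, "ctrl_inv")) {
    NA_real_
  } else {
    activation_threshold(module, x)
  }
  structure(list(module_id = module$module_id, gene_id = module$gene_id,
                 approach = module$approach,
                 n_variants = length(module$variants), thr = thr,
                 contingency = ct, fep = fep(ct),
                 fer = fer(ct, fer_correction)),
            class = "module_score")
}

#' @export
print.module_score <- function(x, ...) {
  cat(sprintf("<module_score> %s: FEP %.4g, FER %.4g (a=%d b=%d c=%d d=%d)\n",
              x$module_id, x$fep, x$fer, x$contingency$a, x$contingency$b,
              x$contingency$c, x$contingency$d))
  invisible(x)
}

#' Score a list of candidates into a data.frame
#'
#' @param candidates list of `module_candidate` objects.
#' @param x a [cohort] with phenotype.
#' @param fer_correction passed to [fer()].
#' @return A data.frame with one row per candidate (module_id, gene,
#'   approach, n_variants, thr, a, b, c, d, fep, fer).
#' @export
score_modules <- function(candidates, x, fer_correction = FALSE) {
  rows <- lapply(candidates, function(m) {
    s <- score_module(m, x, fer_correction)
    data.frame(module_id = s$module_id, gene_id = s$gene_id,
               approach = s$approach, n_variants = s$n_variants,
               thr = s$thr, a = s$contingency$a, b = s$contingency$b,
               c = s$contingency$c, d = s$contingency$d,
               fep = s$fep, fer = s$fer)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname score_modules
#' @param scores data.frame from [score_modules()].
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
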