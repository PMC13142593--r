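#' Coverage of a signature in a cohort
#'
#' @param sig a [ProteinSignature-class].
#' @param m a [CohortMatrix-class].
#' @return one-row data.frame: \code{signature}, \code{cohort_id},
#'   \code{n_total}, \code{n_covered} and a list-column \code{missing} of
#'   the absent symbols in signature order.
#' @export
signatureCoverage <- function(sig, m) {
  genes <- geneSymbols(sig)
  present <- genes %in% rownames(m)
  data.frame(signature = signatureName(sig), cohort_id = cohortId(m),
             n_total = length(genes), n_covered = sum(present),
             missing = I(list(genes[!present])), stringsAsFactors = FALSE)
}

#' Protein sharing across signatures
#'
#' Counts, per gene symbol, how many of the given signatures contain it --
#' the overlap bookkeeping behind UpSet-style sharing summaries.
#'
#' @param sigs list of at least two [ProteinSignature-class] objects.
#' @return named integer vector sorted by decreasing count.
#' @export
signatureOverlap <- function(sigs) {
  if (length(sigs) < 2L) stop("at least two signatures are required")
  tab <- table(unlist(lapply(sigs, geneSymbols)))
  counts <- sort(as.integer(tab), decreasing = TRUE)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(-out, names(out))]
}

#' Head-to-head signature benchmarking
#'
#' Evaluates every signature on every cohort under identical conditions:
#' the same preprocessing, regime (repeated CV or frozen external model),
#' ridge, thresholding rules and -- crucially -- the same fold assignments
#' within a cohort, whose seed is derived from the master seed and the
#' cohort name only (never the signature). Signatures with zero coverage in
#' a cohort yield an explicit non-evaluable row, never a silent skip.
#'
#' @param sigs named list of [ProteinSignature-class] objects.
#' @param cohorts named list; each element is a list with \code{matrix}
#'   (z-scored [CohortMatrix-class]), \code{labels} (case/control),
#'   \code{comparison} (free label), \code{mode} (\code{"cv"} or
#'   \code{"external"}) and, for external mode, \code{train} = list(
#'   \code{matrix}, \code{labels}).
#' @param seed master seed.
#' @param k,repeats,ridge evaluation parameters shared by every cell.
#' @return data.frame, one row per (signature, cohort), with the
#'   diagnostic metrics, coverage and a \code{note} column flagging
#'   non-evaluable cells.
#' @export
runBenchmark <- function(sigs, cohorts, seed = 1, k = 5, repeats = 10,
                         ridge = 1e-3) {
  rows <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    mode <- if (is.null(co$mode)) "cv" else co$mode
    cellSeed <- deriveSeed(seed, cn)
    for (sn in names(sigs)) {
      sig <- sigs[[sn]]
      cov <- signatureCoverage(sig, co$matrix)
      if (cov$n_covered == 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          signature = sn, cohort_id = cohortId(co$matrix),
          comparison = co$comparison, auc = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, threshold = NA_real_,
          sensitivity = NA_real_, specificity = NA_real_,
          youden_j = NA_real_, n_case = sum(co$labels == "case"),
          n_control = sum(co$labels == "control"),
          coverage_fraction = 0, method = mode,
          note = "not evaluable: zero coverage", stringsAsFactors = FALSE)
        next
      }
      res <- if (mode == "cv") {
        repeatedCvAuc(co$matrix, co$labels, sig, k = k, repeats = repeats,
                      ridge = ridge, seed = cellSeed,
                      comparison = co$comparison)
      } else {
        model <- fitPanelModel(co$train$matrix, co$train$labels, sig,
                               ridge = ridge)
        externalValidation(model, co$matrix, co$labels,
                           comparison = co$comparison)
      }
      res <- res[, c("cohort_id", "comparison", "auc", "ci_low", "ci_high",
                     "threshold", "sensitivity", "specificity", "youden_j",
                     "n_case", "n_control", "coverage_fraction", "method")]
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(signature = sn, stringsAsFactors = FALSE), res,
        data.frame(note = "", stringsAsFactors = FALSE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
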