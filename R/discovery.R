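#' Per-protein differential abundance between cases and controls
#'
#' For every protein with at least three observed values per group, the
#' log2 fold change is the case-minus-control mean difference on the log2
#' scale and the p-value comes from a two-sided Welch t-test on the
#' observed values. Proteins with fewer than three observed values in
#' either group are skipped with a warning.
#'
#' @param m a [CohortMatrix-class] on the log2 scale.
#' @param labels factor/character per subject with levels \code{"case"} and
#'   \code{"control"}.
#' @param lfcThreshold,pThreshold thresholds used to set
#'   \code{passes_filter} (|log2 FC| >= 0.6 inclusive, p < 0.05 strict by
#'   default).
#' @return data.frame with columns \code{gene_symbol}, \code{study_id},
#'   \code{log2fc}, \code{p_value}, \code{passes_filter}.
#' @seealso [filterDAPs()], [voteCount()]
#' @export
differentialAbundance <- function(m, labels, lfcThreshold = 0.6,
                                  pThreshold = 0.05) {
  if (abundanceScale(m) == "raw")
    stop("differential abundance expects log2-scale input")
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(m),
            all(labels %in% c("case", "control")))
  vals <- abundance(m)
  caseIdx <- labels == "case"
  skipped <- character()
  rows <- lapply(seq_len(nrow(vals)), function(i) {
    ca <- vals[i, caseIdx]; co <- vals[i, !caseIdx]
    ca <- ca[!is.na(ca)]; co <- co[!is.na(co)]
    if (length(ca) < 3L || length(co) < 3L) {
      skipped <<- c(skipped, rownames(vals)[i])
      return(NULL)
    }
    p <- tryCatch(stats::t.test(ca, co)$p.value, error = function(e) {
      skipped <<- c(skipped, rownames(vals)[i]); NA_real_
    })
    if (is.na(p)) return(NULL)
    data.frame(gene_symbol = rownames(vals)[i], study_id = cohortId(m),
               log2fc = mean(ca) - mean(co), p_value = p,
               stringsAsFactors = FALSE)
  })
  if (length(skipped))
    warning(length(skipped), " protein(s) skipped (insufficient or ",
            "degenerate observations): ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) ", ...")
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_symbol = character(), study_id = character(),
                      log2fc = numeric(), p_value = numeric(),
                      passes_filter = logical()))
  out$passes_filter <- abs(out$log2fc) >= lfcThreshold &
    out$p_value < pThreshold
  rownames(out) <- NULL
  out
}

#' Apply the biological and statistical DAP filter
#'
#' Keeps records with \code{|log2fc| >= lfcThreshold} (inclusive: 0.6 is
#' read as the boundary of the kept region) and \code{p_value <
#' pThreshold} (strict). Order is preserved; the filter is idempotent.
#'
#' @param records data.frame of DAP records
#'   (see [differentialAbundance()]).
#' @param lfcThreshold log2 fold-change magnitude threshold (default 0.6).
#' @param pThreshold significance threshold (default 0.05).
#' @return the filtered records with \code{passes_filter = TRUE}.
#' @export
filterDAPs <- function(records, lfcThreshold = 0.6, pThreshold = 0.05) {
  keep <- abs(records$log2fc) >= lfcThreshold &
    records$p_value < pThreshold
  out <- records[keep, , drop = FALSE]
  out$passes_filter <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Cross-study vote counting
#'
#' Tallies, per gene symbol, the filtered studies it appears in and the
#' per-study direction of change. A study contributing a gene more than
#' once (multiple analytes) contributes a single sign, taken from its
#' record with the largest fold-change magnitude. Only genes present in at
#' least \code{minStudies} studies are returned.
#'
#' @param perStudy named list of filtered DAP data.frames, one per study.
#' @param minStudies minimum number of studies (>= 2, default 2).
#' @return data.frame with \code{gene_symbol}, \code{n_studies_present},
#'   list-column \code{signs} (one +1/-1 per study, in study order) and
#'   \code{concordant}.
#' @export
voteCount <- function(perStudy, minStudies = 2) {
  if (length(perStudy) < 2L) stop("vote counting needs >= 2 studies")
  stopifnot(minStudies >= 2)
  perGene <- list()
  for (study in names(perStudy)) {
    recs <- perStudy[[study]]
    if (nrow(recs) == 0L) next
    # one sign per (study, gene): largest |log2fc| wins
    ord <- order(recs$gene_symbol, -abs(recs$log2fc))
    recs <- recs[ord, , drop = FALSE]
    recs <- recs[!duplicated(recs$gene_symbol), , drop = FALSE]
    for (i in seq_len(nrow(recs))) {
      g <- recs$gene_symbol[i]
      perGene[[g]] <- c(perGene[[g]], sign(recs$log2fc[i]))
    }
  }
  counts <- lengths(perGene)
  keep <- names(perGene)[counts >= minStudies]
  keep <- sort(keep)
  data.frame(
    gene_symbol = keep,
    n_studies_present = unname(counts[keep]),
    signs = I(unname(perGene[keep])),
    concordant = vapply(perGene[keep],
                        function(s) length(unique(s)) == 1L, logical(1)),
    stringsAsFactors = FALSE)
}

#' Retain direction-concordant tallies
#'
#' @param tallies data.frame from [voteCount()].
#' @return the tallies whose per-study signs all agree.
#' @export
concordantDirection <- function(tallies) {
  out <- tallies[tallies$concordant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep candidates measured in every validation cohort
#'
#' A candidate survives only if its gene symbol is present (i.e. retained
#' after the missingness filter) in each validation matrix.
#'
#' @param candidates character vector of gene symbols, or a tally
#'   data.frame with a \code{gene_symbol} column.
#' @param validationMatrices list of [CohortMatrix-class] objects.
#' @return candidates restricted to full validation coverage (same type as
#'   the input).
#' @export
coverageFilter <- function(candidates, validationMatrices) {
  if (length(validationMatrices) == 0L)
    stop("at least one validation matrix is required")
  genes <- if (is.data.frame(candidates)) candidates$gene_symbol
           else candidates
  covered <- Reduce(`&`, lapply(validationMatrices,
                                function(m) genes %in% rownames(m)))
  if (is.data.frame(candidates)) {
    out <- candidates[covered, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    candidates[covered]
  }
}

#' Greedy AUC-driven panel down-selection
#'
#' Candidates are ranked by univariate cross-validated AUC (ties broken
#' alphabetically), added in rank order, and the smallest prefix whose mean
#' CV AUC is within \code{epsilon} of the best prefix is returned: extra
#' proteins that do not improve diagnostic accuracy are left out. The full
#' selection trace (ranking and prefix AUCs) is stored in the returned
#' signature's notes. Identical fold assignments are used for every prefix
#' so the comparison is fair.
#'
#' @param candidates character vector of candidate gene symbols (>= 1).
#' @param m training [CohortMatrix-class] (z-scored).
#' @param labels case/control labels per subject.
#' @param k,repeats cross-validation folds and repeats.
#' @param epsilon AUC tolerance for "did not improve" (default 0.002).
#' @param ridge ridge penalty of the logistic fits.
#' @param seed integer seed (folds).
#' @param name name given to the selected panel.
#' @return a [ProteinSignature-class] with the selected prefix.
#' @export
downSelectPanel <- function(candidates, m, labels, k = 5, repeats = 5,
                            epsilon = 0.002, ridge = 1e-3, seed = 1,
                            name = "panel") {
  candidates <- unique(candidates)
  candidates <- candidates[candidates %in% rownames(m)]
  if (length(candidates) == 0L) stop("no candidate is present in the matrix")
  if (length(candidates) == 1L)
    return(ProteinSignature(name, candidates,
                            notes = list(trace = "single candidate")))
  uniAuc <- vapply(candidates, function(g) {
    repeatedCvAuc(m, labels, g, k = k, repeats = repeats, ridge = ridge,
                  seed = seed)$auc
  }, numeric(1))
  ord <- order(-uniAuc, candidates)  # ties: alphabetical
  ranked <- candidates[ord]
  prefixAuc <- vapply(seq_along(ranked), function(p) {
    repeatedCvAuc(m, labels, ranked[seq_len(p)], k = k, repeats = repeats,
                  ridge = ridge, seed = seed)$auc
  }, numeric(1))
  if (max(prefixAuc) <= 0.5) {
    warning("no candidate combination exceeds AUC 0.5; ",
            "returning the best single protein")
    best <- 1L
  } else {
    best <- which(prefixAuc >= max(prefixAuc) - epsilon)[1L]
  }
  ProteinSignature(name, ranked[seq_len(best)],
                   notes = list(trace = data.frame(
                     gene_symbol = ranked,
                     univariate_auc = uniAuc[ord],
                     prefix_auc = prefixAuc)))
}

#' Run the full discovery funnel
#'
#' Differential abundance per study, DAP thresholds, cross-study vote
#' counting, directional concordance, validation coverage and AUC-driven
#' down-selection, returning the counts at every stage. Each stage's output
#' is never larger than its input.
#'
#' @param bundles named list of cohort bundles (\code{matrix} +
#'   \code{subjects} with a \code{group} column), e.g. from
#'   [simulateMultiStudy()]; alternatively supply \code{perStudy} directly.
#' @param perStudy optional named list of pre-computed DAP tables (columns
#'   \code{gene_symbol}, \code{log2fc}, \code{p_value}), used instead of
#'   computing from \code{bundles}.
#' @param validationMatrices list of [CohortMatrix-class] for the coverage
#'   filter (may be empty to skip).
#' @param train optional list(matrix=, labels=) enabling down-selection.
#' @param lfcThreshold,pThreshold,minStudies,requireConcordance funnel
#'   parameters.
#' @param epsilon,ridge,seed down-selection parameters.
#' @return list with \code{perStudy}, \code{tallies}, \code{concordant},
#'   \code{candidates}, \code{signature} (or NULL) and \code{counts}
#'   (named integer vector of funnel stage sizes).
#' @export
runDiscovery <- function(bundles = NULL, perStudy = NULL,
                         validationMatrices = list(), train = NULL,
                         lfcThreshold = 0.6, pThreshold = 0.05,
                         minStudies = 2, requireConcordance = TRUE,
                         epsilon = 0.002, ridge = 1e-3, seed = 1) {
  if (is.null(perStudy)) {
    stopifnot(!is.null(bundles))
    perStudy <- lapply(bundles, function(b)
      differentialAbundance(b$matrix, b$subjects$group,
                            lfcThreshold, pThreshold))
    names(perStudy) <- names(bundles)
  }
  nUnique <- length(unique(unlist(lapply(perStudy, `[[`, "gene_symbol"))))
  filtered <- lapply(perStudy, filterDAPs, lfcThreshold = lfcThreshold,
                     pThreshold = pThreshold)
  nDap <- length(unique(unlist(lapply(filtered, `[[`, "gene_symbol"))))
  tallies <- voteCount(filtered, minStudies = minStudies)
  conc <- if (requireConcordance) concordantDirection(tallies) else tallies
  candidates <- conc$gene_symbol
  if (length(validationMatrices))
    candidates <- coverageFilter(candidates, validationMatrices)
  signature <- NULL
  if (!is.null(train) && length(candidates) >= 1L)
    signature <- downSelectPanel(candidates, train$matrix, train$labels,
                                 epsilon = epsilon, ridge = ridge,
                                 seed = seed)
  list(perStudy = filtered, tallies = tallies, concordant = conc,
       candidates = candidates, signature = signature,
       counts = c(unique_proteins = nUnique, daps = nDap,
                  shared = nrow(tallies), concordant = nrow(conc),
                  covered = length(candidates),
                  panel = if (is.null(signature)) NA_integer_
                          else length(geneSymbols(signature))))
}
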