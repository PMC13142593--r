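#' Remove proteins with excessive missingness
#'
#' Drops proteins whose fraction of missing subjects is strictly greater
#' than \code{maxMissingFraction} (default 0.8, i.e. proteins with more than
#' 80\% missing values are excluded; a protein at exactly the boundary is
#' retained). The subject set is unchanged and the removed proteins are
#' logged in the provenance.
#'
#' @param x a [CohortMatrix-class].
#' @param maxMissingFraction in \code{[0, 1)}.
#' @return the filtered \code{CohortMatrix}.
#' @export
filterMissingness <- function(x, maxMissingFraction = 0.8) {
  stopifnot(maxMissingFraction >= 0, maxMissingFraction < 1)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty matrix")
  frac <- rowMeans(is.na(abundance(x)))
  drop <- frac > maxMissingFraction
  out <- x[!drop, ]
  out@provenance <- c(out@provenance,
    sprintf("filterMissingness(>%g): removed %d protein(s)%s",
            maxMissingFraction, sum(drop),
            if (any(drop)) paste0(": ",
              paste(rownames(x)[drop], collapse = ", ")) else ""))
  out
}

#' Quantile-normalize subject columns
#'
#' Forces every subject column onto a common distribution: the reference at
#' each rank is the across-column mean of the available order statistics,
#' ranks within a column are preserved, and ties receive the average of the
#' reference values they span. Missing entries stay missing and never enter
#' the reference. When columns differ in their number of observed values the
#' reference is evaluated at each column's quantiles by linear interpolation
#' (exact rank matching applies whenever the counts agree, which makes the
#' normalization exact: all columns then share the same sorted multiset).
#'
#' @param x a [CohortMatrix-class] with at least two subjects.
#' @return the normalized \code{CohortMatrix}.
#' @export
quantileNormalize <- function(x) {
  vals <- abundance(x)
  if (ncol(vals) < 2L) stop("quantile normalization needs >= 2 subjects")
  nObs <- colSums(!is.na(vals))
  if (any(nObs < 2L))
    stop("column(s) with < 2 observed values: ",
         paste(colnames(vals)[nObs < 2L], collapse = ", "))
  nMax <- max(nObs)
  # per-rank reference on a common grid of length nMax
  grid <- (seq_len(nMax) - 1) / (nMax - 1)
  refMat <- vapply(seq_len(ncol(vals)), function(j) {
    s <- sort(vals[, j])
    if (length(s) == nMax) s
    else stats::approx(x = (seq_along(s) - 1) / (length(s) - 1), y = s,
                       xout = grid)$y
  }, numeric(nMax))
  ref <- rowMeans(refMat)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    obs <- which(!is.na(vals[, j]))
    nj <- length(obs)
    target <- if (nj == nMax) ref
              else stats::approx(x = grid, y = ref,
                                 xout = (seq_len(nj) - 1) / (nj - 1))$y
    o <- obs[order(vals[obs, j])]
    # tied input values receive the mean of the reference values they span
    tieGroup <- match(vals[o, j], unique(vals[o, j]))
    out[o, j] <- stats::ave(target, tieGroup)
  }
  .updateValues(x, out, note = "quantileNormalize")
}

#' Log2-transform raw abundances
#'
#' @param x a [CohortMatrix-class] on the raw scale.
#' @param pseudocount added before taking logs (default 0).
#' @return the transformed \code{CohortMatrix}, scale set to \code{"log2"}.
#' @export
log2Transform <- function(x, pseudocount = 0) {
  if (abundanceScale(x) != "raw")
    stop("log2Transform expects scale 'raw', got '", abundanceScale(x), "'")
  vals <- abundance(x)
  shifted <- vals + pseudocount
  bad <- which(!is.na(shifted) & shifted <= 0)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(vals)) + 1
    j <- ((bad[1] - 1) %/% nrow(vals)) + 1
    stop(sprintf(
      "non-positive value at protein '%s', subject '%s' (pseudocount %g)",
      rownames(vals)[i], colnames(vals)[j], pseudocount))
  }
  .updateValues(x, log2(shifted), scale = "log2",
                note = sprintf("log2Transform(pseudocount=%g)", pseudocount))
}

#' Standardize each protein to zero mean and unit variance
#'
#' Within-cohort, per-protein z-scoring on observed values using the n-1
#' standard deviation: the harmonization step that puts cohorts measured on
#' different platforms on a common scale. Zero-variance proteins are an
#' error (drop or handle them explicitly before standardizing).
#'
#' @param x a [CohortMatrix-class] on the log2 (or already z) scale.
#' @return the standardized \code{CohortMatrix}, scale set to
#'   \code{"zscore"}.
#' @export
zscoreStandardize <- function(x) {
  if (abundanceScale(x) == "raw")
    stop("z-scoring expects log2-scale input; run log2Transform first")
  vals <- abundance(x)
  nObs <- rowSums(!is.na(vals))
  if (any(nObs < 2L))
    stop("protein(s) with < 2 observed values: ",
         paste(rownames(vals)[nObs < 2L], collapse = ", "))
  mu <- rowMeans(vals, na.rm = TRUE)
  sd <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  zero <- sd == 0
  if (any(zero))
    stop("zero-variance protein(s): ",
         paste(rownames(vals)[zero], collapse = ", "))
  .updateValues(x, (vals - mu) / sd, scale = "zscore",
                note = "zscoreStandardize")
}

#' Center each protein within batches
#'
#' A deliberately simple batch adjustment: per protein, subtract the batch
#' median on the log2 scale. It removes additive batch offsets and nothing
#' else.
#'
#' @param x a [CohortMatrix-class] on the log2 scale.
#' @param batch factor of batch labels, one per subject.
#' @return the centered \code{CohortMatrix}.
#' @export
batchCenter <- function(x, batch) {
  stopifnot(length(batch) == ncol(x))
  vals <- abundance(x)
  for (b in unique(batch)) {
    idx <- which(batch == b)
    med <- apply(vals[, idx, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    vals[, idx] <- vals[, idx] - med
  }
  .updateValues(x, vals, note = sprintf("batchCenter(%d batches)",
                                        length(unique(batch))))
}

#' Run the fixed preprocessing pipeline
#'
#' Missingness filter, quantile normalization, log2 transform, optional
#' per-batch median centering, then per-protein z-scoring -- in that fixed
#' order, each step logged in the provenance. Re-running the z-score stage
#' on its own output is a numerical no-op.
#'
#' @param x a raw-scale [CohortMatrix-class].
#' @param maxMissingFraction missingness cut-off (see [filterMissingness()]).
#' @param pseudocount for [log2Transform()].
#' @param batch optional batch labels enabling [batchCenter()].
#' @param dropZeroVariance drop zero-variance proteins (after log2) instead
#'   of erroring in the z-score stage.
#' @return a z-scored \code{CohortMatrix}.
#' @export
preprocessCohort <- function(x, maxMissingFraction = 0.8, pseudocount = 0,
                             batch = NULL, dropZeroVariance = TRUE) {
  x <- filterMissingness(x, maxMissingFraction)
  x <- quantileNormalize(x)
  x <- log2Transform(x, pseudocount)
  if (!is.null(batch)) x <- batchCenter(x, batch)
  if (dropZeroVariance) {
    sd <- apply(abundance(x), 1L, stats::sd, na.rm = TRUE)
    nObs <- rowSums(!is.na(abundance(x)))
    bad <- sd == 0 | nObs < 2L
    if (any(bad)) {
      x <- x[!bad, ]
      x@provenance <- c(x@provenance,
        sprintf("dropped %d zero-variance/under-observed protein(s)",
                sum(bad)))
    }
  }
  zscoreStandardize(x)
}
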