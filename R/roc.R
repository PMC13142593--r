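#' ROC curve and AUC
#'
#' The AUC is the probability that a randomly chosen case outscores a
#' randomly chosen control, with ties counted one half (the Mann-Whitney
#' identity); it is computed from mid-ranks. ROC points are evaluated at
#' every unique score taken as a cut-off (a subject is called positive when
#' its score is at or above the cut-off), plus the degenerate all-positive
#' and all-negative ends.
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels per-subject labels; \code{positive} marks the case level.
#' @param positive value of \code{labels} identifying cases (default
#'   \code{"case"}).
#' @return list with \code{auc} and \code{points} (data.frame of
#'   \code{threshold}, \code{sensitivity}, \code{specificity}).
#' @examples
#' rocAuc(c(3, 1, 2, 4), c("control", "control", "case", "case"))$auc
#' @export
rocAuc <- function(scores, labels, positive = "case") {
  isCase <- labels == positive
  if (!any(isCase) || all(isCase))
    stop("both classes must be present")
  if (anyNA(scores)) stop("scores must not contain NA")
  n1 <- sum(isCase); n0 <- sum(!isCase)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[isCase]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cuts <- c(sort(unique(scores)), Inf)
  points <- data.frame(
    threshold = cuts,
    sensitivity = vapply(cuts, function(t) mean(scores[isCase] >= t),
                         numeric(1)),
    specificity = vapply(cuts, function(t) mean(scores[!isCase] < t),
                         numeric(1)))
  list(auc = auc, points = points)
}

#' Confidence interval for the AUC
#'
#' DeLong's variance from the structural components (default), or a seeded
#' percentile bootstrap (2000 stratified resamples). Intervals are clipped
#' to \code{[0, 1]}; a degenerate zero variance collapses the interval to a
#' point with a warning.
#'
#' @inheritParams rocAuc
#' @param method \code{"delong"} or \code{"bootstrap"}.
#' @param level confidence level (default 0.95).
#' @param nBoot bootstrap resamples.
#' @param seed seed for the bootstrap.
#' @return numeric \code{c(ci_low, ci_high)}.
#' @export
aucConfidence <- function(scores, labels, method = c("delong", "bootstrap"),
                          level = 0.95, nBoot = 2000, seed = 1,
                          positive = "case") {
  method <- match.arg(method)
  isCase <- labels == positive
  x <- scores[isCase]; y <- scores[!isCase]
  if (length(x) == 0L || length(y) == 0L)
    stop("both classes must be present")
  auc <- rocAuc(scores, labels, positive)$auc
  if (method == "delong") {
    psi <- function(a, b) (a > b) + 0.5 * (a == b)
    v10 <- vapply(x, function(a) mean(psi(a, y)), numeric(1))
    v01 <- vapply(y, function(b) mean(psi(x, b)), numeric(1))
    v <- stats::var(v10) / length(x) + stats::var(v01) / length(y)
    if (!is.finite(v) || v <= 0) {
      warning("degenerate AUC variance; interval collapses to a point")
      return(c(ci_low = auc, ci_high = auc))
    }
    z <- stats::qnorm(1 - (1 - level) / 2)
    ci <- auc + c(-1, 1) * z * sqrt(v)
  } else {
    ci <- .withSeed(seed, {
      reps <- vapply(seq_len(nBoot), function(i) {
        xb <- sample(x, replace = TRUE)
        yb <- sample(y, replace = TRUE)
        rocAuc(c(xb, yb), rep(c("case", "control"),
                              c(length(xb), length(yb))))$auc
      }, numeric(1))
      stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                      names = FALSE)
    })
  }
  c(ci_low = max(0, ci[1]), ci_high = min(1, ci[2]))
}

#' Youden-optimal operating point
#'
#' Returns the cut-off maximizing J = sensitivity + specificity - 1 over
#' the ROC points, with ties broken toward higher specificity (the larger
#' cut-off).
#'
#' @param points ROC points data.frame from [rocAuc()].
#' @return named numeric \code{c(threshold, sensitivity, specificity,
#'   youden_j)}.
#' @export
youdenThreshold <- function(points) {
  stopifnot(nrow(points) >= 2L)
  j <- points$sensitivity + points$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(points$specificity[best])]
  c(threshold = points$threshold[pick],
    sensitivity = points$sensitivity[pick],
    specificity = points$specificity[pick],
    youden_j = j[pick])
}
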