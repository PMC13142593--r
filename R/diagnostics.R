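# subjects x proteins design for a gene set: covered rows of the z-scored
# matrix, transposed, with missing entries mean-imputed to 0 (the z-scale
# mean); attribute "coverage" = covered fraction of the requested genes
.panelDesign <- function(m, genes) {
  vals <- if (methods::is(m, "CohortMatrix")) abundance(m) else as.matrix(m)
  covered <- genes[genes %in% rownames(vals)]
  if (length(covered) == 0L)
    stop("no panel protein is present in the matrix")
  X <- t(vals[covered, , drop = FALSE])
  X[is.na(X)] <- 0
  attr(X, "coverage") <- length(covered) / length(genes)
  X
}

.asGenes <- function(signature) {
  if (methods::is(signature, "ProteinSignature")) geneSymbols(signature)
  else as.character(signature)
}

.sigName <- function(signature) {
  if (methods::is(signature, "ProteinSignature")) signatureName(signature)
  else "ad-hoc"
}

.diagnosticRow <- function(cohort_id, comparison, auc, ci, op, n_case,
                           n_control, coverage, method) {
  data.frame(cohort_id = cohort_id, comparison = comparison, auc = auc,
             ci_low = unname(ci[1]), ci_high = unname(ci[2]),
             threshold = unname(op["threshold"]),
             sensitivity = unname(op["sensitivity"]),
             specificity = unname(op["specificity"]),
             youden_j = unname(op["youden_j"]),
             n_case = n_case, n_control = n_control,
             coverage_fraction = coverage, method = method,
             stringsAsFactors = FALSE)
}

#' Fit a panel scoring model
#'
#' Ridge-penalized logistic regression of case status on the z-scored
#' abundances of the signature's covered proteins, over one or several
#' cohorts concatenated. The small fixed ridge makes the fit exist and be
#' deterministic even under complete separation.
#'
#' @param train a z-scored [CohortMatrix-class], or a list of them
#'   (columns are concatenated; proteins missing from a cohort contribute
#'   0 on the z scale).
#' @param labels case/control labels per subject (concatenated in cohort
#'   order when \code{train} is a list).
#' @param signature a [ProteinSignature-class] or character vector of gene
#'   symbols.
#' @param ridge ridge penalty (default 1e-3).
#' @return a [PanelModel-class].
#' @export
fitPanelModel <- function(train, labels, signature, ridge = 1e-3) {
  genes <- .asGenes(signature)
  mats <- if (methods::is(train, "CohortMatrix")) list(train) else train
  designs <- lapply(mats, function(m) {
    vals <- abundance(m)
    covered <- genes[genes %in% rownames(vals)]
    X <- matrix(0, ncol(vals), length(genes),
                dimnames = list(colnames(vals), genes))
    X[, covered] <- t(vals[covered, , drop = FALSE])
    X[is.na(X)] <- 0
    X
  })
  X <- do.call(rbind, designs)
  anyCovered <- colnames(X)[colSums(X != 0) > 0]
  if (length(anyCovered) == 0L)
    stop("no signature protein is covered by the training data")
  X <- X[, anyCovered, drop = FALSE]
  y <- as.integer(as.character(labels) == "case")
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  beta <- .ridgeLogit(X, y, lambda = ridge)
  methods::new("PanelModel", signatureName = .sigName(signature),
               proteins = anyCovered, coefficients = beta[-1L],
               intercept = unname(beta[1L]), ridge = ridge,
               training = list(
                 cohorts = vapply(mats, cohortId, character(1)),
                 n = length(y),
                 coverage = length(anyCovered) / length(genes)))
}

#' Score subjects with a fitted panel model
#'
#' The linear predictor over the model's proteins that are available in the
#' matrix; unavailable proteins (and missing entries) contribute zero,
#' i.e. the z-scale mean. The covered fraction of the model's proteins is
#' attached as attribute \code{"coverage_fraction"}.
#'
#' @param model a [PanelModel-class].
#' @param m a z-scored [CohortMatrix-class].
#' @return named numeric vector of subject scores.
#' @export
scoreSubjects <- function(model, m) {
  vals <- abundance(m)
  covered <- model@proteins[model@proteins %in% rownames(vals)]
  if (length(covered) == 0L)
    stop("no model protein is present in the matrix")
  X <- t(vals[covered, , drop = FALSE])
  X[is.na(X)] <- 0
  scores <- drop(X %*% model@coefficients[covered]) + model@intercept
  names(scores) <- colnames(vals)
  attr(scores, "coverage_fraction") <-
    length(covered) / length(model@proteins)
  scores
}

# stratified fold assignment: within each class, a random permutation of
# fold ids 1..k of the right length
.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k)
      stop("class with fewer subjects (", length(idx),
           ") than folds (", k, "); use a smaller k")
    fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Repeated stratified cross-validated AUC
#'
#' Five-fold cross-validation with ten repetitions by default: folds are
#' stratified by class and re-randomized each repeat from the seed;
#' out-of-fold scores are pooled within a repeat and the reported AUC is
#' the mean over repeats. The confidence interval is DeLong's on the
#' per-subject mean out-of-fold score; the across-repeat dispersion
#' interval is also attached (\code{ci_repeat_low}/\code{high} columns).
#'
#' @param m a z-scored [CohortMatrix-class] (or plain matrix).
#' @param labels case/control labels per subject.
#' @param signature panel ([ProteinSignature-class] or gene symbols).
#' @param k folds (default 5).
#' @param repeats repetitions (default 10).
#' @param ridge ridge penalty of the fold fits.
#' @param seed integer seed; identical seeds give identical results.
#' @param comparison free-text comparison label.
#' @return one-row data.frame (cohort, comparison, AUC, CI, Youden
#'   operating point on the mean out-of-fold scores, group sizes,
#'   coverage, and the across-repeat interval).
#' @export
repeatedCvAuc <- function(m, labels, signature, k = 5, repeats = 10,
                          ridge = 1e-3, seed = 1, comparison = "") {
  genes <- .asGenes(signature)
  X <- .panelDesign(m, genes)
  y <- as.integer(as.character(labels) == "case")
  .withSeed(seed, {
    repAuc <- numeric(repeats)
    scoreSum <- numeric(length(y))
    for (r in seq_len(repeats)) {
      fold <- .stratifiedFolds(y, k)
      oof <- numeric(length(y))
      for (f in seq_len(k)) {
        hold <- fold == f
        beta <- .ridgeLogit(X[!hold, , drop = FALSE], y[!hold],
                            lambda = ridge)
        oof[hold] <- drop(cbind(1, X[hold, , drop = FALSE]) %*% beta)
      }
      repAuc[r] <- rocAuc(oof, y, positive = 1)$auc
      scoreSum <- scoreSum + oof
    }
    meanScore <- scoreSum / repeats
    roc <- rocAuc(meanScore, y, positive = 1)
    ci <- suppressWarnings(
      aucConfidence(meanScore, y, method = "delong", positive = 1))
    op <- youdenThreshold(roc$points)
    out <- .diagnosticRow(
      if (methods::is(m, "CohortMatrix")) cohortId(m) else "matrix",
      comparison, mean(repAuc), ci, op, sum(y == 1), sum(y == 0),
      attr(X, "coverage"), sprintf("cv(k=%d,repeats=%d)", k, repeats))
    sdr <- stats::sd(repAuc)
    out$ci_repeat_low <- mean(repAuc) - 1.96 * sdr / sqrt(repeats)
    out$ci_repeat_high <- mean(repAuc) + 1.96 * sdr / sqrt(repeats)
    out
  })
}

#' External validation of a fitted panel model
#'
#' Scores an independently z-scored test cohort with a frozen model (no
#' refitting; the labels enter only the metric stage) and reports AUC with
#' DeLong interval and the Youden operating point.
#'
#' @param model a [PanelModel-class].
#' @param m test [CohortMatrix-class], z-scored independently of training.
#' @param labels case/control labels per test subject.
#' @param comparison free-text comparison label.
#' @return one-row data.frame (see [repeatedCvAuc()]).
#' @export
externalValidation <- function(model, m, labels, comparison = "") {
  scores <- scoreSubjects(model, m)
  y <- as.integer(as.character(labels) == "case")
  roc <- rocAuc(scores, y, positive = 1)
  ci <- suppressWarnings(
    aucConfidence(scores, y, method = "delong", positive = 1))
  op <- youdenThreshold(roc$points)
  .diagnosticRow(cohortId(m), comparison, roc$auc, ci, op,
                 sum(y == 1), sum(y == 0),
                 attr(scores, "coverage_fraction"), "external")
}

#' PCA + one-way MANOVA group-separation test
#'
#' Principal components of the subjects in protein z-score space, followed
#' by a one-way MANOVA on the leading components with Pillai's trace and
#' its standard F approximation. Proteins with any missing value are
#' excluded from the PCA.
#'
#' @param m a z-scored [CohortMatrix-class].
#' @param groups group label per subject (>= 2 groups).
#' @param nComponents leading components tested (default 2; must be below
#'   \code{n -} number of groups).
#' @return one-row data.frame: \code{pillai_trace}, \code{approx_f},
#'   \code{df1}, \code{df2}, \code{p_value}, \code{n_components}.
#' @export
pcaManova <- function(m, groups, nComponents = 2) {
  vals <- if (methods::is(m, "CohortMatrix")) abundance(m) else as.matrix(m)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("at least two groups are required")
  if (nComponents >= ncol(vals) - nlevels(groups))
    stop("too many components for the sample size")
  complete <- stats::complete.cases(vals)
  vals <- vals[complete, , drop = FALSE]
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE)
  nc <- min(nComponents, ncol(pc$x))
  scores <- pc$x[, seq_len(nc), drop = FALSE]
  if (nc == 1L) {
    # single component: Pillai's trace reduces to the between/total
    # sum-of-squares ratio of that component
    fit <- stats::aov(scores[, 1] ~ groups)
    ss <- summary(fit)[[1]][["Sum Sq"]]
    pillai <- ss[1] / sum(ss)
    df <- summary(fit)[[1]][["Df"]]
    fstat <- summary(fit)[[1]][["F value"]][1]
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    out <- data.frame(pillai_trace = pillai, approx_f = fstat,
                      df1 = df[1], df2 = df[2], p_value = p,
                      n_components = 1L)
  } else {
    fit <- stats::manova(scores ~ groups)
    s <- summary(fit, test = "Pillai")$stats
    out <- data.frame(pillai_trace = s["groups", "Pillai"],
                      approx_f = s["groups", "approx F"],
                      df1 = s["groups", "num Df"],
                      df2 = s["groups", "den Df"],
                      p_value = s["groups", "Pr(>F)"],
                      n_components = nc)
  }
  rownames(out) <- NULL
  out
}
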