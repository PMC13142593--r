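#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment of a family of p-values: sorted ascending,
#' \code{adj_i = min_{j >= i} (m p_j / j)}, capped at 1 and returned in the
#' original order. Values outside (0, 1] are an error.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted protein-clinical association
#'
#' Per protein and clinical variable, a least-squares fit of log2 protein
#' abundance on the variable with age and sex as covariates, on complete
#' cases. The coefficient is the change in log2 abundance per unit of the
#' variable. P-values are adjusted per variable across proteins by
#' Benjamini-Hochberg. With \code{moderate = TRUE}, residual variances are
#' pooled across proteins by limma's empirical-Bayes shrinkage instead of
#' the per-protein OLS variance.
#'
#' @param m a log2-scale (or z-scored) [CohortMatrix-class].
#' @param clinical data.frame, one row per subject, with \code{subject_id},
#'   the clinical variables and the covariates.
#' @param variables clinical variable names to test (default: every column
#'   other than \code{subject_id} and the covariates).
#' @param covariates covariate names (default age and sex).
#' @param moderate use limma's moderated statistics.
#' @return long data.frame: \code{gene_symbol}, \code{variable},
#'   \code{beta}, \code{se}, \code{p_value}, \code{adjusted_p}, \code{n}.
#'   Variables with a degenerate (constant) design are flagged via
#'   attribute \code{"excluded"} and excluded from their BH family.
#' @export
clinicalAssociation <- function(m, clinical, variables = NULL,
                                covariates = c("age", "sex"),
                                moderate = FALSE) {
  if (abundanceScale(m) == "raw")
    stop("association expects log2-scale input")
  stopifnot("subject_id" %in% names(clinical))
  covariates <- intersect(covariates, names(clinical))
  if (is.null(variables))
    variables <- setdiff(names(clinical), c("subject_id", covariates))
  vals <- abundance(m)
  clinical <- clinical[match(colnames(vals), clinical$subject_id), ,
                       drop = FALSE]
  absent <- setdiff(variables, names(clinical))
  if (length(absent))
    stop("clinical table lacks variable(s): ",
         paste(absent, collapse = ", "))
  excluded <- character()
  out <- lapply(variables, function(v) {
    covDf <- clinical[, covariates, drop = FALSE]
    if ("sex" %in% covariates)
      covDf$sex <- as.integer(as.character(covDf$sex) == "M")
    okSubj <- !is.na(clinical[[v]]) & stats::complete.cases(covDf)
    x <- clinical[[v]][okSubj]
    if (length(unique(x)) < 2L) {
      excluded <<- c(excluded, v)
      return(NULL)
    }
    design <- cbind(Intercept = 1, variable = x,
                    as.matrix(covDf[okSubj, , drop = FALSE]))
    sub <- vals[, okSubj, drop = FALSE]
    if (moderate) {
      fit <- limma::eBayes(limma::lmFit(sub, design))
      res <- data.frame(
        gene_symbol = rownames(sub), variable = v,
        beta = fit$coefficients[, "variable"],
        se = fit$stdev.unscaled[, "variable"] * sqrt(fit$s2.post),
        p_value = fit$p.value[, "variable"],
        n = rowSums(!is.na(sub)), stringsAsFactors = FALSE)
    } else {
      res <- do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
        yObs <- !is.na(sub[i, ])
        nOk <- sum(yObs)
        if (nOk < ncol(design) + 2L) return(NULL)
        fit <- stats::lm.fit(design[yObs, , drop = FALSE], sub[i, yObs])
        rdf <- fit$df.residual
        sigma2 <- sum(fit$residuals^2) / rdf
        XtXinv <- chol2inv(chol(crossprod(design[yObs, , drop = FALSE])))
        se <- sqrt(sigma2 * XtXinv[2, 2])
        tstat <- fit$coefficients["variable"] / se
        data.frame(gene_symbol = rownames(sub)[i], variable = v,
                   beta = unname(fit$coefficients["variable"]), se = se,
                   p_value = 2 * stats::pt(-abs(tstat), rdf), n = nOk,
                   stringsAsFactors = FALSE)
      }))
    }
    if (is.null(res) || nrow(res) == 0L) return(NULL)
    res$adjusted_p <- bhAdjust(pmax(res$p_value, .Machine$double.xmin))
    res
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene_symbol = character(), variable = character(),
                      beta = numeric(), se = numeric(),
                      p_value = numeric(), n = integer(),
                      adjusted_p = numeric())
  rownames(res) <- NULL
  attr(res, "excluded") <- excluded
  if (length(excluded))
    warning("variable(s) with degenerate design excluded: ",
            paste(excluded, collapse = ", "))
  res
}

#' Scale association effects for cross-variable comparison
#'
#' Standardized beta = beta x sd(variable) / sd(protein), a unitless effect
#' allowing ranking across clinical variables with different units.
#' Idempotent: already-standardized results are returned unchanged.
#'
#' @param results data.frame from [clinicalAssociation()].
#' @param m the [CohortMatrix-class] the associations were computed on.
#' @param clinical the clinical table used.
#' @return \code{results} with a \code{standardized_beta} column;
#'   zero-variance variables are flagged with \code{NA}.
#' @export
scaleEffects <- function(results, m, clinical) {
  if ("standardized_beta" %in% names(results)) return(results)
  vals <- abundance(m)
  protSd <- apply(vals, 1L, stats::sd, na.rm = TRUE)
  varSd <- vapply(unique(results$variable), function(v)
    stats::sd(clinical[[v]], na.rm = TRUE), numeric(1))
  s <- varSd[results$variable] / protSd[results$gene_symbol]
  s[!is.finite(s) | varSd[results$variable] == 0] <- NA_real_
  results$standardized_beta <- results$beta * s
  results
}
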