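#' CohortMatrix: a protein-by-subject abundance matrix with cohort identity
#'
#' The unit of data every stage of the package consumes. A
#' \code{CohortMatrix} is a \linkS4class{SummarizedExperiment} carrying one
#' \code{"abundance"} assay (proteins as rows, subjects as columns), the
#' cohort identifier, the proteomic platform, the scale the values are on
#' (\code{"raw"}, \code{"log2"} or \code{"zscore"}), and a provenance log of
#' every transformation applied. Subject metadata (A/T status, clinical
#' status, age, sex, CSF biomarker values) lives in \code{colData}; optional
#' UniProt / analyte annotations live in \code{rowData}.
#'
#' @slot cohortId single character, the cohort identifier.
#' @slot platform one of \code{"mass_spec"}, \code{"aptamer"}, \code{"pea"}.
#' @slot abundanceScale one of \code{"raw"}, \code{"log2"}, \code{"zscore"}.
#' @slot provenance character vector of transformation log lines.
#'
#' @seealso [CohortMatrix()] for the constructor, [preprocessCohort()] for
#'   the harmonization pipeline.
#' @export
setClass("CohortMatrix",
  contains = "SummarizedExperiment",
  slots = c(
    cohortId = "character",
    platform = "character",
    abundanceScale = "character",
    provenance = "character"
  )
)

.PLATFORMS <- c("mass_spec", "aptamer", "pea")
.SCALES <- c("raw", "log2", "zscore")

setValidity("CohortMatrix", function(object) {
  msg <- character()
  if (length(object@cohortId) != 1L || !nzchar(object@cohortId))
    msg <- c(msg, "cohortId must be a single non-empty string")
  if (!(object@platform %in% .PLATFORMS))
    msg <- c(msg, sprintf("platform must be one of %s",
                          paste(.PLATFORMS, collapse = ", ")))
  if (!(object@abundanceScale %in% .SCALES))
    msg <- c(msg, sprintf("scale must be one of %s",
                          paste(.SCALES, collapse = ", ")))
  rn <- rownames(object)
  cn <- colnames(object)
  if (is.null(rn) || anyNA(rn) || !all(nzchar(rn)))
    msg <- c(msg, "all proteins must have non-empty gene symbols")
  if (!is.null(rn) && anyDuplicated(rn))
    msg <- c(msg, sprintf("duplicated gene symbols: %s",
                          paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  if (!is.null(cn) && anyDuplicated(cn))
    msg <- c(msg, sprintf("duplicated subject ids: %s",
                          paste(unique(cn[duplicated(cn)]), collapse = ", ")))
  if (!("abundance" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'abundance' is required")
  if (length(msg)) msg else TRUE
})

#' ATRule: a CSF biomarker threshold rule for amyloid/tau classification
#'
#' Encodes one biological classification rule of the form
#' \code{numerator / denominator > threshold} (or a single-biomarker
#' comparison), assigning either joint A/T status or amyloid status alone.
#' Comparisons are strict in the stated direction; a subject exactly at the
#' threshold is negative.
#'
#' @slot numerator biomarker name (one of \code{"abeta42"}, \code{"abeta40"},
#'   \code{"ttau"}, \code{"ptau"}).
#' @slot denominator optional biomarker name (\code{NA_character_} for a
#'   single-biomarker rule).
#' @slot threshold positive cut-off on the (ratio) value.
#' @slot direction \code{"greater_is_positive"} or \code{"less_is_positive"}.
#' @slot assigns \code{"AT_joint"} (sets both A and T) or \code{"A_only"}.
#' @seealso [atRule()], [classifyATStatus()]
#' @export
setClass("ATRule", slots = c(
  numerator = "character",
  denominator = "character",
  threshold = "numeric",
  direction = "character",
  assigns = "character"
))

setValidity("ATRule", function(object) {
  msg <- character()
  if (!nzchar(object@numerator)) msg <- c(msg, "numerator must be named")
  if (!is.na(object@threshold) && object@threshold <= 0)
    msg <- c(msg, "threshold must be > 0")
  if (!(object@direction %in% c("greater_is_positive", "less_is_positive")))
    msg <- c(msg, "invalid direction")
  if (!(object@assigns %in% c("AT_joint", "A_only")))
    msg <- c(msg, "assigns must be 'AT_joint' or 'A_only'")
  if (length(msg)) msg else TRUE
})

#' ProteinSignature: a named protein panel
#'
#' A published (or discovered) biomarker panel: an ordered list of unique
#' gene symbols with provenance. The packaged registry
#' ([signatureRegistry()]) holds the 11-protein vote-counting panel plus the
#' thirteen published comparator signatures.
#'
#' @slot name panel name.
#' @slot genes ordered character vector of unique gene symbols.
#' @slot source citation string (free text).
#' @slot objective what the panel was proposed for.
#' @slot notes list of free-form annotations (e.g. discovery method,
#'   selection trace).
#' @export
setClass("ProteinSignature", slots = c(
  name = "character",
  genes = "character",
  source = "character",
  objective = "character",
  notes = "list"
))

setValidity("ProteinSignature", function(object) {
  msg <- character()
  if (length(object@genes) == 0L) msg <- c(msg, "gene list must be non-empty")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene symbols must be unique")
  if (!all(nzchar(object@genes))) msg <- c(msg, "empty gene symbol")
  if (length(msg)) msg else TRUE
})

#' PanelModel: a fitted panel scoring model
#'
#' A ridge-penalized logistic regression fit on z-scored protein abundances.
#' The linear predictor over the covered proteins is the panel score used by
#' the diagnostic and prognostic stages. Proteins absent from an evaluation
#' cohort contribute zero (mean imputation on the z scale).
#'
#' @slot signatureName name of the signature the model was fit for.
#' @slot proteins proteins actually used (post coverage).
#' @slot coefficients named numeric vector, one per protein.
#' @slot intercept numeric scalar.
#' @slot ridge the ridge penalty used.
#' @slot training list of provenance fields (cohorts, n, seed).
#' @export
setClass("PanelModel", slots = c(
  signatureName = "character",
  proteins = "character",
  coefficients = "numeric",
  intercept = "numeric",
  ridge = "numeric",
  training = "list"
))

setValidity("PanelModel", function(object) {
  msg <- character()
  if (!all(is.finite(object@coefficients)) || !is.finite(object@intercept))
    msg <- c(msg, "coefficients must be finite")
  if (length(object@coefficients) != length(object@proteins))
    msg <- c(msg, "one coefficient per protein required")
  if (length(msg)) msg else TRUE
})
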