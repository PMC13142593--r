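#' Packaged cohort registry
#'
#' The demographic registry of the cohorts behind the framework: eight
#' discovery studies, two training cohorts, three diagnostic validation
#' cohorts and one differential-diagnosis (Parkinson's disease) cohort, with
#' per-study subject counts by amyloid/tau stratum, sex counts, and
#' platform. Printed per-role totals are carried as an attribute
#' (\code{attr(x, "totals")}) so that recomputed sums can be checked against
#' them.
#'
#' @param path optional path to a registry JSON in the packaged schema;
#'   defaults to the registry shipped with the package.
#' @return data.frame, one row per study, with attribute \code{"totals"}.
#' @examples
#' reg <- cohortRegistry()
#' summarizeRegistry(reg, roles = "discovery", field = "n_total")  # 759
#' @export
cohortRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cohort_registry.json",
                        package = "PanelVote", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  reg <- raw$studies
  attr(reg, "totals") <- raw$totals
  reg
}

.REGISTRY_FIELDS <- c("n_total", "aneg_tneg", "apos_tpos", "aneg_tneg_cu",
                      "apos_tpos_ci", "apos_tpos_mci", "apos_tpos_dem",
                      "n_female", "n_male")

#' Sum a registry field over cohort roles
#'
#' Sums the requested stratum over the per-study rows whose role is in
#' \code{roles}. Studies that did not report the stratum (NA) contribute 0
#' and are reported via a message.
#'
#' @param registry data.frame from [cohortRegistry()].
#' @param roles character vector of roles (\code{"discovery"},
#'   \code{"training"}, \code{"validation"}, \code{"differential"}).
#' @param field stratum name, one of \code{n_total}, \code{aneg_tneg},
#'   \code{apos_tpos}, \code{aneg_tneg_cu}, \code{apos_tpos_ci},
#'   \code{apos_tpos_mci}, \code{apos_tpos_dem}, \code{n_female},
#'   \code{n_male}.
#' @return integer sum.
#' @export
summarizeRegistry <- function(registry, roles, field) {
  if (!(field %in% .REGISTRY_FIELDS) || !(field %in% names(registry)))
    stop("unknown field '", field, "'")
  sub <- registry[registry$role %in% roles, , drop = FALSE]
  vals <- sub[[field]]
  if (anyNA(vals))
    message(sprintf("summarizeRegistry: %d stud(ies) with NA '%s' count as 0",
                    sum(is.na(vals)), field))
  as.integer(sum(vals, na.rm = TRUE))
}

#' Packaged signature registry
#'
#' The 11-protein vote-counting panel plus the thirteen published CSF
#' proteomic signatures used for head-to-head benchmarking, as
#' [ProteinSignature-class] objects.
#'
#' @param path optional path to a JSON registry (a list of objects with
#'   \code{name}, \code{source}, \code{objective}, \code{genes} and optional
#'   \code{notes}); defaults to the packaged registry.
#' @return named list of [ProteinSignature-class] objects.
#' @examples
#' sigs <- signatureRegistry()
#' length(sigs)                      # 14
#' geneSymbols(sigs[["PPAV11"]])
#' @export
signatureRegistry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "signature_registry.json",
                        package = "PanelVote", mustWork = TRUE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  sigs <- lapply(raw, function(s) {
    ProteinSignature(
      name = s$name, genes = unlist(s$genes),
      source = if (is.null(s$source)) "" else s$source,
      objective = if (is.null(s$objective)) "" else s$objective,
      notes = s[setdiff(names(s), c("name", "genes", "source", "objective"))])
  })
  names(sigs) <- vapply(sigs, signatureName, character(1))
  sigs
}
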