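#' Construct a CohortMatrix
#'
#' @param values numeric matrix, proteins as rows (rownames = gene symbols),
#'   subjects as columns (colnames = subject ids). \code{NA} marks a missing
#'   measurement.
#' @param cohortId cohort identifier.
#' @param platform \code{"mass_spec"}, \code{"aptamer"} or \code{"pea"}.
#' @param scale scale of \code{values}: \code{"raw"}, \code{"log2"} or
#'   \code{"zscore"}.
#' @param uniprot optional character vector of UniProt accessions, one per
#'   protein.
#' @param subjectData optional data.frame of per-subject metadata (rows
#'   matched to columns of \code{values}).
#' @param provenance character vector of log lines carried over.
#'
#' @return a [CohortMatrix-class] object.
#' @examples
#' m <- matrix(2^rnorm(6, 10), 3, 2,
#'             dimnames = list(c("NPTX2", "PKM", "YWHAG"), c("s1", "s2")))
#' cm <- CohortMatrix(m, cohortId = "toy", platform = "mass_spec")
#' abundanceScale(cm)
#' @export
CohortMatrix <- function(values, cohortId, platform = "mass_spec",
                         scale = "raw", uniprot = NULL, subjectData = NULL,
                         provenance = character()) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rd <- S4Vectors::DataFrame(row.names = rownames(values))
  if (!is.null(uniprot)) rd$uniprot <- uniprot
  if (is.null(subjectData)) {
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
  } else {
    cd <- S4Vectors::DataFrame(subjectData)
    rownames(cd) <- colnames(values)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values), rowData = rd, colData = cd)
  methods::new("CohortMatrix", se,
               cohortId = as.character(cohortId),
               platform = match.arg(platform, .PLATFORMS),
               abundanceScale = match.arg(scale, .SCALES),
               provenance = provenance)
}

#' @describeIn CohortMatrix cohort identifier.
#' @param x a \code{CohortMatrix}.
#' @export
setMethod("cohortId", "CohortMatrix", function(x) x@cohortId)

#' @describeIn CohortMatrix proteomic platform.
#' @export
setMethod("platform", "CohortMatrix", function(x) x@platform)

#' @describeIn CohortMatrix scale the abundance values are on.
#' @export
setMethod("abundanceScale", "CohortMatrix", function(x) x@abundanceScale)

#' @describeIn CohortMatrix transformation log.
#' @export
setMethod("provenance", "CohortMatrix", function(x) x@provenance)

#' @describeIn CohortMatrix the protein-by-subject abundance matrix.
#' @export
setMethod("abundance", "CohortMatrix", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @describeIn CohortMatrix gene symbols (row names).
#' @export
setMethod("geneSymbols", "CohortMatrix", function(x) rownames(x))

setMethod("show", "CohortMatrix", function(object) {
  cat(sprintf("CohortMatrix '%s' [%s, %s scale]: %d proteins x %d subjects\n",
              object@cohortId, object@platform, object@abundanceScale,
              nrow(object), ncol(object)))
  miss <- mean(is.na(abundance(object)))
  cat(sprintf("  missing: %.1f%%; provenance: %d step(s)\n",
              100 * miss, length(object@provenance)))
})

# replace the assay, optionally the scale, and append a provenance line
.updateValues <- function(x, values, scale = NULL, note = NULL) {
  SummarizedExperiment::assay(x, "abundance") <- values
  if (!is.null(scale)) x@abundanceScale <- scale
  if (!is.null(note)) x@provenance <- c(x@provenance, note)
  methods::validObject(x)
  x
}

#' @describeIn ProteinSignature panel name.
#' @param x a \code{ProteinSignature}.
#' @export
setMethod("signatureName", "ProteinSignature", function(x) x@name)

#' @describeIn ProteinSignature gene symbols composing the panel.
#' @export
setMethod("geneSymbols", "ProteinSignature", function(x) x@genes)

#' Construct a ProteinSignature
#'
#' @param name panel name.
#' @param genes character vector of unique gene symbols.
#' @param source citation string.
#' @param objective what the panel targets.
#' @param notes list of annotations.
#' @return a [ProteinSignature-class].
#' @export
ProteinSignature <- function(name, genes, source = "", objective = "",
                             notes = list()) {
  methods::new("ProteinSignature", name = name, genes = as.character(genes),
               source = source, objective = objective, notes = notes)
}

setMethod("show", "ProteinSignature", function(object) {
  cat(sprintf("ProteinSignature '%s' (%d proteins)\n", object@name,
              length(object@genes)))
  cat(" ", paste(object@genes, collapse = ", "), "\n")
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "PanelModel", function(object) {
  cat(sprintf("PanelModel for '%s': %d proteins, ridge %g\n",
              object@signatureName, length(object@proteins), object@ridge))
})
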