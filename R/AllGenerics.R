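#' @export
setGeneric("cohortId", function(x) standardGeneric("cohortId"))

#' @export
setGeneric("platform", function(x) standardGeneric("platform"))

#' @export
setGeneric("abundanceScale", function(x) standardGeneric("abundanceScale"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("abundance", function(x) standardGeneric("abundance"))

#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @export
setGeneric("signatureName", function(x) standardGeneric("signatureName"))
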