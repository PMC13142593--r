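#' Read a protein abundance matrix from TSV/CSV
#'
#' Expects proteins as rows by default: the header row holds subject ids,
#' the first column gene symbols, and an optional second column named
#' \code{uniprot}. The missing-value tokens \code{""}, \code{"NA"},
#' \code{"NaN"} and \code{"na"} become missing entries; any other
#' non-numeric cell is an error naming its location. Duplicate gene symbols
#' are an error unless \code{collapse = TRUE}, in which case the analyte
#' with the highest observed variance is kept per symbol (the multi-analyte
#' collapse rule used for aptamer platforms).
#'
#' @param path file path.
#' @param cohortId cohort identifier for the returned object.
#' @param platform platform of the cohort.
#' @param orientation \code{"proteins_as_rows"} (default) or
#'   \code{"subjects_as_rows"}.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @param scale declared scale of the stored values (default \code{"raw"}).
#' @param collapse collapse duplicated gene symbols by highest variance.
#' @return a [CohortMatrix-class].
#' @seealso [writeCohortMatrix()] for the byte-stable counterpart.
#' @export
readCohortMatrix <- function(path, cohortId, platform = "mass_spec",
                             orientation = c("proteins_as_rows",
                                             "subjects_as_rows"),
                             format = c("tsv", "csv"), scale = "raw",
                             collapse = FALSE) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           comment.char = "")
  idCol <- tab[[1L]]
  uniprot <- NULL
  dataStart <- 2L
  if (ncol(tab) >= 2L && tolower(names(tab)[2L]) == "uniprot") {
    uniprot <- tab[[2L]]
    dataStart <- 3L
  }
  cellCols <- names(tab)[dataStart:ncol(tab)]
  chr <- as.matrix(tab[, dataStart:ncol(tab), drop = FALSE])
  vals <- .parseCells(as.vector(chr), idCol, cellCols)
  if (orientation == "subjects_as_rows") {
    vals <- t(vals)
    uniprot <- NULL
  }
  dup <- unique(rownames(vals)[duplicated(rownames(vals))])
  if (length(dup)) {
    if (!collapse)
      stop("duplicated gene symbols: ", paste(dup, collapse = ", "))
    keep <- .collapseByVariance(vals)
    vals <- vals[keep, , drop = FALSE]
    if (!is.null(uniprot)) uniprot <- uniprot[keep]
  }
  CohortMatrix(vals, cohortId = cohortId, platform = platform, scale = scale,
               uniprot = uniprot,
               provenance = sprintf("read %s (%s)", basename(path), format))
}

# indices keeping, per duplicated gene symbol, the row with highest variance;
# ties broken toward the first occurrence
.collapseByVariance <- function(vals) {
  v <- apply(vals, 1L, stats::var, na.rm = TRUE)
  v[is.na(v)] <- -Inf
  keep <- tapply(seq_len(nrow(vals)), rownames(vals),
                 function(idx) idx[which.max(v[idx])])
  sort(unname(keep))
}

#' Write a CohortMatrix to TSV/CSV
#'
#' Values are serialized at 15 significant digits so a write/read round trip
#' reproduces them element-wise to well within 1e-9.
#'
#' @param x a [CohortMatrix-class].
#' @param path destination path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeCohortMatrix <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  vals <- abundance(x)
  out <- data.frame(gene_symbol = rownames(vals), check.names = FALSE,
                    stringsAsFactors = FALSE)
  rd <- SummarizedExperiment::rowData(x)
  if ("uniprot" %in% colnames(rd)) out$uniprot <- rd$uniprot
  chr <- matrix(formatC(vals, digits = 15, format = "g"), nrow = nrow(vals))
  chr[is.na(vals)] <- "NA"
  colnames(chr) <- colnames(vals)
  out <- cbind(out, as.data.frame(chr, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a subject metadata table
#'
#' Columns recognized: \code{subject_id}, \code{cohort_id},
#' \code{amyloid_status}, \code{tau_status}, \code{clinical_status},
#' \code{age}, \code{sex}, and CSF biomarkers \code{abeta42}, \code{abeta40},
#' \code{ttau}, \code{ptau} (pg/mL). Unknown columns are carried through.
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return data.frame, one row per subject.
#' @export
readSubjectTable <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!"subject_id" %in% names(tab)) stop("column 'subject_id' is required")
  if ("age" %in% names(tab) && any(tab$age <= 0, na.rm = TRUE))
    stop("age must be positive")
  tab
}

#' Read a long-format visits table
#'
#' @param path file path with columns \code{subject_id}, \code{time_years},
#'   \code{clinical_status} and optionally \code{amyloid_status},
#'   \code{tau_status}.
#' @param format \code{"tsv"} or \code{"csv"}.
#' @return data.frame sorted by subject and visit time.
#' @export
readVisitsTable <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "time_years", "clinical_status")
  if (!all(need %in% names(tab)))
    stop("columns required: ", paste(need, collapse = ", "))
  tab[order(tab$subject_id, tab$time_years), , drop = FALSE]
}
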