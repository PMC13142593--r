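#' Derive a stage seed from a master seed and a stage name
#'
#' Every stochastic stage of a pipeline run takes its own seed derived
#' deterministically from the master seed and the stage name, so that
#' re-running a single stage reproduces exactly what the full pipeline did.
#' The scheme is a 31-bit polynomial rolling hash of the stage name folded
#' into the master seed; it is stable across platforms and R versions.
#'
#' @param master integer master seed.
#' @param stage stage name (character).
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @examples
#' deriveSeed(1L, "discover")
#' @export
deriveSeed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master), is.character(stage))
  mod <- 2147483647  # 2^31 - 1, prime
  h <- as.double(master) %% mod
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% mod
  as.integer(h)
}

# run code under a seed without disturbing the caller's RNG state
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# tokens treated as missing when parsing abundance tables
.MISSING_TOKENS <- c("", "NA", "NaN", "na")

# parse a character matrix of cells into numeric, erroring with the location
# of the first non-numeric, non-missing token
.parseCells <- function(chr, rowIds, colIds) {
  chr <- trimws(chr)
  isMissing <- chr %in% .MISSING_TOKENS
  num <- suppressWarnings(as.numeric(chr))
  bad <- which(is.na(num) & !isMissing)
  if (length(bad)) {
    i <- ((bad[1] - 1) %% length(rowIds)) + 1
    j <- ((bad[1] - 1) %/% length(rowIds)) + 1
    stop(sprintf("non-numeric cell '%s' at protein '%s', subject '%s'",
                 chr[bad[1]], rowIds[i], colIds[j]))
  }
  num[isMissing] <- NA_real_
  matrix(num, nrow = length(rowIds),
         dimnames = list(rowIds, colIds))
}
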