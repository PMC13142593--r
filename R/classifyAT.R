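#' Construct an amyloid/tau classification rule
#'
#' @param numerator CSF biomarker name (\code{"abeta42"}, \code{"abeta40"},
#'   \code{"ttau"}, \code{"ptau"}).
#' @param denominator optional biomarker name for a ratio rule.
#' @param threshold positive cut-off.
#' @param direction \code{"greater_is_positive"} (default) or
#'   \code{"less_is_positive"}.
#' @param assigns \code{"AT_joint"} (default) or \code{"A_only"}.
#' @return an [ATRule-class].
#' @examples
#' adniATRule()   # p-Tau181/Abeta42 > 0.023
#' bangsATRule()  # t-Tau/Abeta42 > 0.226
#' @export
atRule <- function(numerator, denominator = NA_character_, threshold,
                   direction = c("greater_is_positive", "less_is_positive"),
                   assigns = c("AT_joint", "A_only")) {
  methods::new("ATRule", numerator = numerator,
               denominator = as.character(denominator),
               threshold = threshold,
               direction = match.arg(direction),
               assigns = match.arg(assigns))
}

#' @rdname atRule
#' @export
adniATRule <- function() atRule("ptau", "abeta42", 0.023)

#' @rdname atRule
#' @export
bangsATRule <- function() atRule("ttau", "abeta42", 0.226)

#' Assign amyloid/tau status from CSF biomarkers
#'
#' Computes the rule's biomarker (ratio) per subject and compares it to the
#' threshold with a strict inequality in the rule's direction. A subject
#' above the cut-off (for \code{greater_is_positive}) is positive; a subject
#' exactly at the threshold is negative. Subjects lacking the required
#' biomarker(s) are left \code{"unknown"}. Classification is total on
#' subjects with complete inputs: every such subject becomes \code{"pos"}
#' or \code{"neg"}.
#'
#' @param subjects data.frame with a \code{subject_id} column and the
#'   biomarker columns the rule names (pg/mL).
#' @param rule an [ATRule-class].
#' @return \code{subjects} with \code{amyloid_status} (and, for
#'   \code{AT_joint} rules, \code{tau_status}) filled in.
#' @export
classifyATStatus <- function(subjects, rule) {
  stopifnot(methods::is(rule, "ATRule"))
  num <- subjects[[rule@numerator]]
  if (is.null(num))
    stop("subjects lack biomarker '", rule@numerator, "'")
  if (is.na(rule@denominator)) {
    value <- num
  } else {
    den <- subjects[[rule@denominator]]
    if (is.null(den))
      stop("subjects lack biomarker '", rule@denominator, "'")
    zero <- which(!is.na(den) & den == 0)
    if (length(zero))
      stop("zero denominator for subject(s): ",
           paste(subjects$subject_id[zero], collapse = ", "))
    value <- num / den
  }
  pos <- if (rule@direction == "greater_is_positive")
    value > rule@threshold else value < rule@threshold
  status <- ifelse(is.na(pos), "unknown", ifelse(pos, "pos", "neg"))
  subjects$amyloid_status <- status
  if (rule@assigns == "AT_joint") subjects$tau_status <- status
  subjects
}
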