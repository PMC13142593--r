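#' Median split into high- and low-score groups
#'
#' Subjects strictly above the mid-rank sample median are \code{"high"};
#' subjects at or below it (including ties at the median) are \code{"low"}.
#'
#' @param scores named numeric vector of subject scores (>= 2).
#' @return named factor with levels \code{c("low", "high")}.
#' @export
medianStratify <- function(scores) {
  if (length(scores) < 2L) stop("at least two subjects are required")
  med <- stats::median(scores)
  if (all(scores == scores[1L]))
    stop("all scores identical; no stratification possible")
  grp <- factor(ifelse(scores > med, "high", "low"),
                levels = c("low", "high"))
  names(grp) <- names(scores)
  grp
}

#' Mean direction-aligned z-score of a panel
#'
#' The model-free panel score: the mean of the member proteins' z-scores,
#' each multiplied by its discovery direction (+1 up in disease, -1 down),
#' over the proteins covered by the matrix. Missing values contribute the
#' z-scale mean (0).
#'
#' @param m a z-scored [CohortMatrix-class].
#' @param signature a [ProteinSignature-class] or gene symbols.
#' @param directions optional named numeric of +/-1 per gene; defaults to
#'   +1 for every protein.
#' @return named numeric vector of subject scores with attribute
#'   \code{"coverage_fraction"}.
#' @export
meanZScore <- function(m, signature, directions = NULL) {
  genes <- .asGenes(signature)
  X <- .panelDesign(m, genes)
  d <- rep(1, ncol(X))
  names(d) <- colnames(X)
  if (!is.null(directions)) {
    common <- intersect(names(directions), names(d))
    d[common] <- sign(directions[common])
  }
  scores <- drop(X %*% d) / ncol(X)
  names(scores) <- rownames(X)
  attr(scores, "coverage_fraction") <- attr(X, "coverage")
  scores
}

#' Cox proportional-hazards fit for high vs low groups
#'
#' Partial-likelihood estimation (Breslow tie handling by default, Efron by
#' flag) of the hazard ratio of the high- versus low-score group, adjusted
#' for age and sex when present. The 95\% CI is \code{exp(coef +/- 1.96
#' SE)}; significance is the two-sided Wald test. If all events fall in a
#' single group (monotone likelihood) a warning is raised and a
#' ridge-penalized fit is used as fallback.
#'
#' @param records data.frame of survival records: \code{time} (> 0, years),
#'   \code{event} (0/1), \code{group} (\code{"low"}/\code{"high"}), and
#'   optionally \code{age}, \code{sex}.
#' @param covariates covariate names to adjust for (subset of
#'   \code{c("age", "sex")}; only those present in \code{records} are
#'   used).
#' @param ties \code{"breslow"} (default) or \code{"efron"}.
#' @param label transition label carried into the result.
#' @return one-row data.frame: \code{hr}, \code{ci_low}, \code{ci_high},
#'   \code{wald_p}, \code{coef}, \code{se}, \code{n_high}, \code{n_low},
#'   \code{n_events}, \code{transition}.
#' @export
coxFit <- function(records, covariates = c("age", "sex"),
                   ties = c("breslow", "efron"), label = "") {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event", "group") %in% names(records)),
            all(records$time > 0))
  records$group <- factor(as.character(records$group),
                          levels = c("low", "high"))
  if (any(table(records$group) == 0L)) stop("both groups must be present")
  if (sum(records$event) == 0L) stop("no events in the data")
  covariates <- intersect(covariates, names(records))
  eventsByGroup <- tapply(records$event, records$group, sum)
  monotone <- any(eventsByGroup == 0L)
  rhs <- paste(c("group", covariates), collapse = " + ")
  if (monotone) {
    warning("all events in one group (monotone likelihood); ",
            "using a ridge-penalized fit")
    records$group01 <- as.integer(records$group == "high")
    rhs <- paste(c("survival::ridge(group01, theta = 1)", covariates),
                 collapse = " + ")
  }
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = records, ties = ties)
  co <- summary(fit)$coefficients
  row <- grep("group", rownames(co))[1L]
  coef <- co[row, "coef"]
  se <- co[row, grep("^se", colnames(co))[1L]]
  data.frame(hr = exp(coef), ci_low = exp(coef - 1.96 * se),
             ci_high = exp(coef + 1.96 * se),
             wald_p = 2 * stats::pnorm(-abs(coef / se)),
             coef = coef, se = se,
             n_high = sum(records$group == "high"),
             n_low = sum(records$group == "low"),
             n_events = sum(records$event), transition = label,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates with S(0) = 1, steps at event times only, and
#' censoring marks retained.
#'
#' @param records survival records (see [coxFit()]); the \code{group}
#'   column defines the strata.
#' @return data.frame with \code{group}, \code{time}, \code{n_risk},
#'   \code{n_event}, \code{n_censor}, \code{survival} (the time-0 row is
#'   included for each group).
#' @export
kaplanMeier <- function(records) {
  stopifnot(nrow(records) >= 1L)
  records$group <- factor(as.character(records$group))
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group, data = records)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(records$group)[1],
                                    length(s$time))
         else sub("^group=", "", as.character(s$strata))
  out <- data.frame(group = grp, time = s$time, n_risk = s$n.risk,
                    n_event = s$n.event, n_censor = s$n.censor,
                    survival = s$surv, stringsAsFactors = FALSE)
  zero <- data.frame(group = unique(grp), time = 0,
                     n_risk = as.vector(table(records$group)[unique(grp)]),
                     n_event = 0, n_censor = 0, survival = 1,
                     stringsAsFactors = FALSE)
  out <- rbind(zero, out)
  out[order(out$group, out$time), , drop = FALSE]
}

.transitionStates <- function(transition) {
  switch(transition,
    CU_to_ATMCI = list(
      origin = list(clinical = "CU", amyloid = "neg", tau = "neg"),
      dest = list(clinical = "MCI", amyloid = "pos", tau = "pos")),
    ATMCI_to_ATdementia = list(
      origin = list(clinical = "MCI", amyloid = "pos", tau = "pos"),
      dest = list(clinical = "dementia", amyloid = "pos", tau = "pos")),
    stop("unknown transition: ", transition))
}

#' Build a time-to-event dataset for a clinical transition
#'
#' Eligible subjects sit at the transition's origin state at baseline,
#' have at least two visits, and a follow-up between 0.5 and 12.5 years.
#' The event is the first visit at the destination state (for
#' \code{CU_to_ATMCI}: clinically MCI and A+T+; for
#' \code{ATMCI_to_ATdementia}: A+T+ dementia); otherwise the subject is
#' censored at the last visit. Subjects with a non-monotone state sequence
#' are included with their first qualifying event, with a warning.
#'
#' @param visits long-format data.frame: \code{subject_id},
#'   \code{time_years}, \code{clinical_status}, \code{amyloid_status},
#'   \code{tau_status}.
#' @param transition \code{"CU_to_ATMCI"} or \code{"ATMCI_to_ATdementia"}.
#' @param scores named numeric of baseline panel scores; stratified by
#'   [medianStratify()] within the eligible subset.
#' @param subjects optional data.frame with \code{subject_id}, \code{age},
#'   \code{sex} merged onto the records.
#' @param minFollowup,maxFollowup follow-up window in years.
#' @return survival-record data.frame as consumed by [coxFit()].
#' @export
buildTransitionDataset <- function(visits, transition, scores,
                                   subjects = NULL, minFollowup = 0.5,
                                   maxFollowup = 12.5) {
  st <- .transitionStates(transition)
  visits <- visits[order(visits$subject_id, visits$time_years), ,
                   drop = FALSE]
  rows <- lapply(split(visits, visits$subject_id), function(v) {
    if (nrow(v) < 2L) return(NULL)
    if (is.unsorted(v$time_years)) stop("visit times must be non-decreasing")
    base <- v[1L, ]
    if (base$clinical_status != st$origin$clinical) return(NULL)
    fu <- v$time_years[nrow(v)] - v$time_years[1L]
    if (fu < minFollowup || fu > maxFollowup) return(NULL)
    isDest <- v$clinical_status == st$dest$clinical &
      v$amyloid_status == st$dest$amyloid &
      v$tau_status == st$dest$tau
    isDest[1L] <- FALSE
    if (any(isDest)) {
      first <- which(isDest)[1L]
      if (first < nrow(v) && any(!isDest[(first + 1L):nrow(v)]))
        warning("subject ", base$subject_id,
                " has a non-monotone state sequence; first qualifying ",
                "event used")
      data.frame(subject_id = base$subject_id,
                 time = v$time_years[first] - v$time_years[1L],
                 event = 1L, stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = base$subject_id, time = fu, event = 0L,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L)
    stop("no eligible subject for transition ", transition)
  rownames(out) <- NULL
  sc <- scores[out$subject_id]
  if (anyNA(sc)) stop("scores missing for ",
                      sum(is.na(sc)), " eligible subject(s)")
  out$score <- unname(sc)
  out$group <- medianStratify(stats::setNames(out$score, out$subject_id))
  if (!is.null(subjects))
    out <- merge(out, subjects[, intersect(c("subject_id", "age", "sex"),
                                           names(subjects))],
                 by = "subject_id", sort = FALSE)
  out
}
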