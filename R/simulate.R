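#' Configuration for one simulated proteomic study
#'
#' Defines a two-group (case = A+T+, control = A-T-) cohort on the log2
#' abundance scale with planted differential proteins, Gaussian noise,
#' platform gain/offset and per-protein completely-at-random missingness.
#' Defaults emulate a moderately powered discovery study: 30 subjects per
#' arm (the inclusion floor is three per group), planted effects of 1 log2
#' unit (comfortably above the 0.6 detectability floor of the downstream
#' filter), residual noise of 0.4 log2 units, and ~5\% average missingness.
#'
#' @param cohort_id cohort identifier.
#' @param platform proteomic platform label.
#' @param n_case,n_control subjects per arm (>= 3).
#' @param n_proteins size of the protein universe (filler proteins are
#'   named \code{PROT0001}, ...).
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @param planted_markers data.frame with columns \code{gene_symbol} and
#'   \code{effect} (signed case-minus-control shift, log2 units,
#'   \code{|effect|} >= 0.6).
#' @param noise_sd residual standard deviation, log2 units.
#' @param study_specific_hits number of additional markers unique to this
#'   study (planted at effect size \code{+/-1} with random sign).
#' @param missing_beta length-2 shape parameters of the Beta distribution
#'   of per-protein missing fractions.
#' @param platform_offset additive scale shift applied after simulation.
#' @param platform_gain multiplicative factor applied after simulation.
#' @return a \code{simStudyConfig} list.
#' @export
simStudyConfig <- function(cohort_id, platform = "mass_spec", n_case = 30,
                           n_control = 30, n_proteins = 200, seed = 1,
                           planted_markers = NULL, noise_sd = 0.4,
                           study_specific_hits = 0,
                           missing_beta = c(1, 19), platform_offset = 0,
                           platform_gain = 1) {
  if (n_case < 3 || n_control < 3)
    stop("at least three subjects per group are required")
  if (!is.null(planted_markers)) {
    stopifnot(is.data.frame(planted_markers),
              all(c("gene_symbol", "effect") %in% names(planted_markers)))
    if (any(abs(planted_markers$effect) < 0.6))
      stop("planted effects must be at least 0.6 log2 units in magnitude")
  }
  structure(list(cohort_id = cohort_id, platform = platform,
                 n_case = n_case, n_control = n_control,
                 n_proteins = n_proteins, seed = as.integer(seed),
                 planted_markers = planted_markers, noise_sd = noise_sd,
                 study_specific_hits = study_specific_hits,
                 missing_beta = missing_beta,
                 platform_offset = platform_offset,
                 platform_gain = platform_gain),
            class = "simStudyConfig")
}

#' Simulate one two-group proteomic cohort
#'
#' Protein values are Normal(baseline + group x effect, noise_sd) on the
#' log2 scale; the platform gain and offset are then applied and
#' missingness masked. Case subjects are labelled A+T+ with cognitive
#' impairment, controls A-T- cognitively unimpaired.
#'
#' @param cfg a [simStudyConfig()].
#' @return list with elements \code{matrix} (a [CohortMatrix-class] on the
#'   log2 scale), \code{subjects} (metadata data.frame) and \code{truth}
#'   (data.frame of every planted marker with its signed effect and kind).
#' @export
simulateCohort <- function(cfg) {
  stopifnot(inherits(cfg, "simStudyConfig"))
  planted <- cfg$planted_markers
  if (is.null(planted))
    planted <- data.frame(gene_symbol = character(),
                          effect = numeric())
  planted$kind <- rep("shared", nrow(planted))
  .withSeed(cfg$seed, {
    if (cfg$study_specific_hits > 0) {
      eff <- sample(c(-1, 1), cfg$study_specific_hits, replace = TRUE)
      planted <- rbind(planted, data.frame(
        gene_symbol = sprintf("SS_%s_%02d", cfg$cohort_id,
                              seq_len(cfg$study_specific_hits)),
        effect = eff, kind = "study_specific"))
    }
    if (nrow(planted) > cfg$n_proteins)
      stop("more planted markers than proteins in the universe")
    nFiller <- cfg$n_proteins - nrow(planted)
    proteins <- c(planted$gene_symbol,
                  sprintf("PROT%04d", seq_len(nFiller)))
    n <- cfg$n_case + cfg$n_control
    group <- rep(c(1, 0), c(cfg$n_case, cfg$n_control))
    baseline <- stats::rnorm(cfg$n_proteins, mean = 10, sd = 1)
    effect <- c(planted$effect, rep(0, nFiller))
    vals <- baseline + outer(effect, group) +
      matrix(stats::rnorm(cfg$n_proteins * n, sd = cfg$noise_sd),
             cfg$n_proteins, n)
    vals <- cfg$platform_gain * vals + cfg$platform_offset
    missFrac <- stats::rbeta(cfg$n_proteins, cfg$missing_beta[1],
                             cfg$missing_beta[2])
    mask <- matrix(stats::runif(length(vals)), nrow(vals)) < missFrac
    vals[mask] <- NA_real_
    dimnames(vals) <- list(proteins,
                           sprintf("%s_S%03d", cfg$cohort_id, seq_len(n)))
    subjects <- data.frame(
      subject_id = colnames(vals), cohort_id = cfg$cohort_id,
      group = ifelse(group == 1, "case", "control"),
      amyloid_status = ifelse(group == 1, "pos", "neg"),
      tau_status = ifelse(group == 1, "pos", "neg"),
      clinical_status = ifelse(group == 1, "dementia", "CU"),
      age = round(pmax(45, stats::rnorm(n, 72, 7)), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    m <- CohortMatrix(vals, cohortId = cfg$cohort_id,
                      platform = cfg$platform, scale = "log2",
                      subjectData = subjects,
                      provenance = sprintf("simulateCohort(seed=%d)",
                                           cfg$seed))
    list(matrix = m, subjects = subjects, truth = planted)
  })
}

#' Simulate several studies sharing a common set of true markers
#'
#' The shared markers are planted in every study. With probability
#' \code{1 - concordance} a shared marker has its sign flipped in exactly
#' one (randomly chosen) study, exercising the directional-concordance
#' filter downstream. Study-specific noise hits are disjoint across studies
#' by construction.
#'
#' @param configs list of [simStudyConfig()] (their \code{planted_markers}
#'   are overwritten by the shared set).
#' @param sharedMarkers data.frame with \code{gene_symbol} and signed
#'   \code{effect}.
#' @param concordance fraction of shared markers left fully concordant,
#'   in \code{[0, 1]}.
#' @param seed seed for the flip assignment.
#' @return named list of cohort bundles as returned by [simulateCohort()],
#'   with an attribute \code{"flipped"} naming the discordant markers.
#' @export
simulateMultiStudy <- function(configs, sharedMarkers, concordance = 1,
                               seed = 1) {
  if (concordance < 0 || concordance > 1)
    stop("concordance must be in [0, 1]")
  stopifnot(all(c("gene_symbol", "effect") %in% names(sharedMarkers)))
  nS <- length(configs)
  flips <- .withSeed(seed, {
    doFlip <- stats::rbinom(nrow(sharedMarkers), 1, 1 - concordance) == 1
    data.frame(gene_symbol = sharedMarkers$gene_symbol[doFlip],
               study = sample(nS, sum(doFlip), replace = TRUE))
  })
  bundles <- lapply(seq_len(nS), function(i) {
    cfg <- configs[[i]]
    planted <- sharedMarkers[, c("gene_symbol", "effect")]
    toFlip <- flips$gene_symbol[flips$study == i]
    planted$effect[planted$gene_symbol %in% toFlip] <-
      -planted$effect[planted$gene_symbol %in% toFlip]
    cfg$planted_markers <- planted
    simulateCohort(cfg)
  })
  names(bundles) <- vapply(configs, `[[`, character(1), "cohort_id")
  attr(bundles, "flipped") <- flips
  bundles
}

#' Configuration for a simulated progression cohort
#'
#' @param n_subjects total subjects.
#' @param group_fraction_high fraction in the high-score group.
#' @param hazard_ratio_true true hazard ratio, high vs low (> 0).
#' @param baseline_hazard events/year in the low group.
#' @param censor_min,censor_max administrative censoring window in years
#'   (defaults: six months to 12.5 years).
#' @param beta_age,beta_sex log-hazard effects of age (per year, centred at
#'   72) and male sex.
#' @param seed integer seed.
#' @return a \code{simProgressionConfig} list.
#' @export
simProgressionConfig <- function(n_subjects, group_fraction_high = 0.5,
                                 hazard_ratio_true = 1,
                                 baseline_hazard = 0.1, censor_min = 0.5,
                                 censor_max = 12.5, beta_age = 0,
                                 beta_sex = 0, seed = 1) {
  if (hazard_ratio_true <= 0) stop("hazard_ratio_true must be > 0")
  structure(list(n_subjects = n_subjects,
                 group_fraction_high = group_fraction_high,
                 hazard_ratio_true = hazard_ratio_true,
                 baseline_hazard = baseline_hazard,
                 censor_min = censor_min, censor_max = censor_max,
                 beta_age = beta_age, beta_sex = beta_sex,
                 seed = as.integer(seed)),
            class = "simProgressionConfig")
}

#' Simulate right-censored progression outcomes
#'
#' Event times are exponential with hazard
#' \code{baseline x HR^group x exp(beta_age (age - 72) + beta_sex male)};
#' administrative censoring is uniform on the follow-up window. Every
#' record has \code{time > 0} and \code{event} in \code{\{0, 1\}}, and no
#' observed time exceeds the window maximum.
#'
#' @param cfg a [simProgressionConfig()].
#' @return data.frame of survival records (\code{subject_id}, \code{time},
#'   \code{event}, \code{group}, \code{age}, \code{sex}).
#' @export
simulateProgressionCohort <- function(cfg) {
  stopifnot(inherits(cfg, "simProgressionConfig"))
  .withSeed(cfg$seed, {
    n <- cfg$n_subjects
    nHigh <- round(cfg$group_fraction_high * n)
    group <- rep(c("high", "low"), c(nHigh, n - nHigh))
    age <- round(pmax(45, stats::rnorm(n, 72, 7)), 1)
    sex <- sample(c("F", "M"), n, replace = TRUE)
    rate <- cfg$baseline_hazard *
      cfg$hazard_ratio_true^(group == "high") *
      exp(cfg$beta_age * (age - 72) + cfg$beta_sex * (sex == "M"))
    tEvent <- stats::rexp(n, rate)
    tCens <- stats::runif(n, cfg$censor_min, cfg$censor_max)
    data.frame(subject_id = sprintf("P%04d", seq_len(n)),
               time = pmin(tEvent, tCens),
               event = as.integer(tEvent <= tCens),
               group = factor(group, levels = c("low", "high")),
               age = age, sex = sex, stringsAsFactors = FALSE)
  })
}

#' Expand survival records into a minimal visit history
#'
#' The inverse convenience of [buildTransitionDataset()]: each record
#' becomes a baseline visit at the transition's origin state plus a final
#' visit at the event or censoring time (destination state if the event
#' occurred, origin state otherwise).
#'
#' @param records data.frame from [simulateProgressionCohort()].
#' @param transition \code{"CU_to_ATMCI"} or \code{"ATMCI_to_ATdementia"}.
#' @return long-format visits data.frame.
#' @export
simulateVisits <- function(records,
                           transition = c("CU_to_ATMCI",
                                          "ATMCI_to_ATdementia")) {
  transition <- match.arg(transition)
  st <- .transitionStates(transition)
  do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    end <- if (r$event == 1) st$dest else st$origin
    data.frame(subject_id = r$subject_id,
               time_years = c(0, r$time),
               clinical_status = c(st$origin$clinical, end$clinical),
               amyloid_status = c(st$origin$amyloid, end$amyloid),
               tau_status = c(st$origin$tau, end$tau),
               stringsAsFactors = FALSE)
  }))
}
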