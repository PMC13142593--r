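# small in-code fixtures shared across test files

toyMatrix <- function(vals = NULL, scale = "raw", cohort = "toy") {
  if (is.null(vals))
    vals <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                   dimnames = list(c("NPTX2", "PKM", "YWHAG"),
                                   c("s1", "s2")))
  CohortMatrix(vals, cohortId = cohort, platform = "mass_spec",
               scale = scale)
}

# a z-scored two-group cohort with planted markers, for model tests
plantedCohort <- function(seed = 1, nPerArm = 50, effect = 1.5,
                          nMarkers = 3, nNoise = 50, noise = 0.5) {
  markers <- data.frame(gene_symbol = sprintf("MARK%02d", seq_len(nMarkers)),
                        effect = effect)
  b <- simulateCohort(simStudyConfig(
    "planted", n_case = nPerArm, n_control = nPerArm,
    n_proteins = nMarkers + nNoise, planted_markers = markers,
    noise_sd = noise, missing_beta = c(1, 99), seed = seed))
  b$matrix <- zscoreStandardize(b$matrix)
  b
}

# brute-force AUC over all case/control pairs, ties counted one half
bruteAuc <- function(scores, labels, positive = "case") {
  x <- scores[labels == positive]
  y <- scores[labels != positive]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# brute-force BH step-up from the definition:
# adj_(i) = min(1, min_{j >= i} m p_(j) / j), returned in input order
bruteBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adjSorted <- vapply(seq_len(m), function(i)
    min(1, min(m * ps[i:m] / (i:m))), numeric(1))
  adj <- numeric(m)
  adj[ord] <- adjSorted
  adj
}

# brute-force two-group Cox partial likelihood (Breslow), no covariates
brutePartialLik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
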