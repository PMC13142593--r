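test_that("AUC equals the pairwise-concordance count and is rank-invariant", {
  expect_equal(rocAuc(c(1, 2, 3, 4),
                      c("control", "control", "case", "case"))$auc, 1)
  expect_equal(rocAuc(c(1, 2, 3, 4),
                      c("case", "case", "control", "control"))$auc, 0)
  expect_equal(rocAuc(c(3, 1, 2, 4),
                      c("control", "control", "case", "case"))$auc, 0.75)

  set.seed(5)
  for (i in 1:20) {
    n1 <- sample(2:50, 1); n0 <- sample(2:50, 1)
    scores <- round(c(rnorm(n1, 1), rnorm(n0)), 1)  # rounding makes ties
    labels <- rep(c("case", "control"), c(n1, n0))
    expect_equal(rocAuc(scores, labels)$auc, bruteAuc(scores, labels))
    # invariance under a strictly monotone transform
    expect_equal(rocAuc(exp(scores / 2), labels)$auc,
                 rocAuc(scores, labels)$auc)
  }
})

test_that("DeLong and bootstrap intervals behave as specified", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- rep(c("control", "case"), each = 3)
  expect_warning(ci <- aucConfidence(scores, labels), "degenerate")
  expect_equal(unname(ci), c(1, 1))

  set.seed(8)
  scores <- c(rnorm(60, 1.2), rnorm(60))
  labels <- rep(c("case", "control"), each = 60)
  ci <- aucConfidence(scores, labels)
  auc <- rocAuc(scores, labels)$auc
  expect_lt(ci[1], auc); expect_gt(ci[2], auc)
  # agrees with the reference DeLong implementation
  ref <- as.numeric(pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<", levels =
                                             c("control", "case"))))
  expect_equal(unname(ci), ref[c(1, 3)], tolerance = 1e-8)

  b1 <- aucConfidence(scores, labels, method = "bootstrap", seed = 3)
  b2 <- aucConfidence(scores, labels, method = "bootstrap", seed = 3)
  expect_identical(b1, b2)

  # coverage: 95% CI covers the true AUC in about 95% of replicates
  covered <- vapply(1:200, function(s) {
    set.seed(s)
    sc <- c(rnorm(40, 1.19), rnorm(40))  # true AUC ~ 0.8
    lb <- rep(c("case", "control"), each = 40)
    ci <- aucConfidence(sc, lb)
    ci[1] <= 0.8 && 0.8 <= ci[2]
  }, logical(1))
  expect_gt(mean(covered), 0.90); expect_lt(mean(covered), 0.99)
})

test_that("Youden threshold matches an exhaustive scan", {
  scan <- function(scores, labels) {
    cuts <- c(sort(unique(scores)), Inf)
    best <- NULL
    for (t in cuts) {
      sens <- mean(scores[labels == "case"] >= t)
      spec <- mean(scores[labels == "control"] < t)
      j <- sens + spec - 1
      if (is.null(best) || j > best["youden_j"] + 1e-12 ||
          (abs(j - best["youden_j"]) <= 1e-12 && spec > best["specificity"]))
        best <- c(threshold = t, sensitivity = sens, specificity = spec,
                  youden_j = j)
    }
    best
  }
  set.seed(11)
  for (i in 1:15) {
    scores <- round(c(rnorm(30, 1), rnorm(30)), 1)
    labels <- rep(c("case", "control"), each = 30)
    roc <- rocAuc(scores, labels)
    expect_equal(youdenThreshold(roc$points), scan(scores, labels))
  }
  # perfectly separated: J = 1; degenerate scores: J = 0
  sep <- rocAuc(c(1, 2, 8, 9), rep(c("control", "case"), each = 2))
  expect_equal(unname(youdenThreshold(sep$points)["youden_j"]), 1)
  flat <- rocAuc(c(5, 5, 5, 5), rep(c("control", "case"), each = 2))
  expect_equal(unname(youdenThreshold(flat$points)["youden_j"]), 0)
})

test_that("ridge logistic fits agree with glm away from separation", {
  set.seed(2)
  X <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, plogis(X %*% c(1, -0.5, 0)))
  ours <- PanelVote:::.ridgeLogit(X, y, lambda = 1e-8)
  ref <- coef(glm(y ~ X, family = binomial()))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("panel model handles separation, nulls and degenerate panels", {
  b <- plantedCohort(seed = 3, effect = 3, noise = 0.2)
  model <- fitPanelModel(b$matrix, b$subjects$group,
                         sprintf("MARK%02d", 1:3))
  expect_true(all(is.finite(model@coefficients)))
  sc <- scoreSubjects(model, b$matrix)
  expect_equal(rocAuc(sc, b$subjects$group)$auc, 1)

  # permuted labels on a non-separable cohort: coefficients near zero
  mild <- plantedCohort(seed = 5, nPerArm = 100, effect = 1, noise = 1)
  perm <- PanelVote:::.withSeed(4, sample(mild$subjects$group))
  nullModel <- fitPanelModel(mild$matrix, perm, sprintf("MARK%02d", 1:3))
  expect_true(all(abs(nullModel@coefficients) < 0.5))

  # one-protein signature equals univariate logistic on that protein
  uni <- fitPanelModel(mild$matrix, mild$subjects$group, "MARK01",
                       ridge = 1e-8)
  x <- abundance(mild$matrix)["MARK01", ]
  x[is.na(x)] <- 0  # the model mean-imputes on the z scale
  y <- as.integer(mild$subjects$group == "case")
  ref <- coef(glm(y ~ x, family = binomial()))
  expect_equal(unname(uni@coefficients), unname(ref[2]), tolerance = 1e-3)

  expect_error(fitPanelModel(b$matrix, rep("case", ncol(b$matrix)),
                             "MARK01"), "single class")
})

test_that("scoring honors coverage and imputes absent proteins at the mean", {
  b <- plantedCohort(seed = 6)
  model <- fitPanelModel(b$matrix, b$subjects$group,
                         c(sprintf("MARK%02d", 1:3), "PROT0001"))
  # all-zero z-values score at the intercept
  zeroM <- CohortMatrix(matrix(0, 4, 2, dimnames = list(
    c(sprintf("MARK%02d", 1:3), "PROT0001"), c("a", "b"))),
    "z", scale = "zscore")
  expect_equal(unname(scoreSubjects(model, zeroM)),
               rep(model@intercept, 2), ignore_attr = TRUE)
  # dropping proteins reduces the recorded coverage
  sub <- b$matrix[c("MARK01", "MARK02"), ]
  sc <- scoreSubjects(model, sub)
  expect_equal(attr(sc, "coverage_fraction"), 0.5)
  expect_error(scoreSubjects(model, b$matrix[c("PROT0005"), ]),
               "no model protein")
})

test_that("repeated CV is deterministic, powerful, and null-calibrated", {
  b <- plantedCohort(seed = 10, nPerArm = 100, effect = 2, nMarkers = 5,
                     noise = 0.5)
  genes <- sprintf("MARK%02d", 1:5)
  r1 <- repeatedCvAuc(b$matrix, b$subjects$group, genes, seed = 42,
                      repeats = 3)
  r2 <- repeatedCvAuc(b$matrix, b$subjects$group, genes, seed = 42,
                      repeats = 3)
  expect_identical(r1, r2)
  expect_gte(r1$auc, 0.99)
  expect_true(r1$ci_low <= r1$auc && r1$auc <= r1$ci_high)

  # permuted labels at n=200: mean AUC within [0.45, 0.55]
  permAuc <- PanelVote:::.withSeed(99, {
    perm <- sample(b$subjects$group)
    repeatedCvAuc(b$matrix, perm, genes, seed = 7)$auc
  })
  expect_gt(permAuc, 0.45); expect_lt(permAuc, 0.55)

  few <- c(1:4, 101:104)  # four cases, four controls
  expect_error(repeatedCvAuc(b$matrix[, few],
                             b$subjects$group[few], genes, k = 5),
               "smaller k")
})

test_that("external validation generalizes and ignores platform shifts", {
  markers <- data.frame(gene_symbol = sprintf("MARK%02d", 1:3),
                        effect = 1.5)
  mk <- function(seed, offset = 0, gain = 1) {
    b <- simulateCohort(simStudyConfig(
      paste0("c", seed), n_case = 100, n_control = 100, n_proteins = 30,
      planted_markers = markers, noise_sd = 0.5, missing_beta = c(1, 999),
      platform_offset = offset, platform_gain = gain, seed = seed))
    b$matrix <- zscoreStandardize(b$matrix)
    b
  }
  train <- mk(21); test <- mk(22)
  model <- fitPanelModel(train$matrix, train$subjects$group,
                         sprintf("MARK%02d", 1:3))
  cv <- repeatedCvAuc(train$matrix, train$subjects$group,
                      sprintf("MARK%02d", 1:3), seed = 1)
  ext <- externalValidation(model, test$matrix, test$subjects$group)
  expect_lt(abs(ext$auc - cv$auc), 0.05)

  # platform gain/offset before z-scoring leaves the AUC unchanged
  shifted <- mk(22, offset = 5, gain = 3)
  extShift <- externalValidation(model, shifted$matrix,
                                 shifted$subjects$group)
  expect_equal(extShift$auc, ext$auc, tolerance = 1e-9)

  # selectivity: identically distributed groups score near chance
  nullB <- mk(23)
  nullLabels <- PanelVote:::.withSeed(31, sample(nullB$subjects$group))
  extNull <- externalValidation(model, nullB$matrix, nullLabels)
  expect_gt(extNull$auc, 0.4); expect_lt(extNull$auc, 0.6)
})

test_that("PCA-MANOVA separates shifted groups and reduces correctly", {
  # power: 3-sd mean shift at n=50/50 is detected
  b <- plantedCohort(seed = 30, nPerArm = 50, effect = 3, nMarkers = 4,
                     noise = 1)
  res <- pcaManova(b$matrix, b$subjects$group, nComponents = 2)
  expect_lt(res$p_value, 0.05)
  expect_lte(res$pillai_trace, 1)

  # one component: Pillai equals the between/total SS ratio
  res1 <- pcaManova(b$matrix, b$subjects$group, nComponents = 1)
  vals <- abundance(b$matrix)[stats::complete.cases(abundance(b$matrix)), ]
  pc1 <- prcomp(t(vals))$x[, 1]
  g <- factor(b$subjects$group)
  ssb <- sum(tapply(pc1, g, function(v) length(v) *
                      (mean(v) - mean(pc1))^2))
  expect_equal(res1$pillai_trace, ssb / sum((pc1 - mean(pc1))^2),
               tolerance = 1e-9)

  # null calibration: p approximately uniform over seeds
  ps <- vapply(1:200, function(s) {
    PanelVote:::.withSeed(s, {
      vals <- matrix(rnorm(20 * 60), 20, 60,
                     dimnames = list(sprintf("p%02d", 1:20),
                                     sprintf("s%02d", 1:60)))
      pcaManova(vals, rep(c("a", "b"), each = 30), nComponents = 3)$p_value
    })
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
  expect_error(pcaManova(b$matrix, b$subjects$group, nComponents = 200),
               "too many components")
})
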