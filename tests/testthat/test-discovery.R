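test_that("differential abundance computes group mean differences and power", {
  # identical groups: log2fc 0, never passes the filter
  vals <- matrix(rep(c(1, 2, 3, 1, 2, 3), 2), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), sprintf("s%d", 1:6)))
  m <- toyMatrix(vals, scale = "log2")
  da <- differentialAbundance(m, rep(c("case", "control"), each = 3))
  expect_equal(da$log2fc, c(0, 0))
  expect_false(any(da$passes_filter))

  # exact arithmetic: case mean 4, control mean 3 -> log2fc = 1
  vals2 <- matrix(c(4, 4, 4, 3, 3, 3), nrow = 1,
                  dimnames = list("g", sprintf("s%d", 1:6)))
  vals2 <- rbind(g = vals2, h = c(4.1, 3.9, 4.0, 3.0, 3.1, 2.9))
  da2 <- suppressWarnings(
    differentialAbundance(toyMatrix(vals2, scale = "log2"),
                          rep(c("case", "control"), each = 3)))
  expect_equal(da2$log2fc[da2$gene_symbol == "h"], 1, tolerance = 1e-9)

  # planted +1.0 shift at n=30/30, sd 0.3 passes in >= 99% of seeds
  pass <- vapply(1:30, function(s) {
    b <- simulateCohort(simStudyConfig("p", n_case = 30, n_control = 30,
                                       n_proteins = 5,
                                       planted_markers = data.frame(
                                         gene_symbol = "UP", effect = 1),
                                       noise_sd = 0.3,
                                       missing_beta = c(1, 999), seed = s))
    da <- differentialAbundance(b$matrix, b$subjects$group)
    da$passes_filter[da$gene_symbol == "UP"]
  }, logical(1))
  expect_gte(mean(pass), 29 / 30)

  # groups under 3 observed values are skipped with a warning
  tiny <- toyMatrix(matrix(1:4, 1, dimnames = list("x", 1:4)),
                    scale = "log2")
  expect_warning(
    out <- differentialAbundance(tiny, c("case", "case", "control",
                                         "control")),
    "skipped")
  expect_equal(nrow(out), 0L)
})

test_that("DAP filter applies inclusive FC and strict p boundaries", {
  recs <- data.frame(
    gene_symbol = c("kept", "lowfc", "boundary", "highp"),
    study_id = "s",
    log2fc = c(0.7, 0.59, 0.60, 2.0),
    p_value = c(0.01, 0.001, 0.049, 0.05))
  out <- filterDAPs(recs)
  expect_setequal(out$gene_symbol, c("kept", "boundary"))
  # idempotent and order-independent
  expect_equal(filterDAPs(out), out)
  shuffled <- recs[c(3, 1, 4, 2), ]
  expect_setequal(filterDAPs(shuffled)$gene_symbol, out$gene_symbol)
})

test_that("vote counting matches a brute-force intersection oracle", {
  set.seed(9)
  genes <- sprintf("G%03d", 1:100)
  perStudy <- lapply(1:5, function(i) {
    g <- sample(genes, 40)
    data.frame(gene_symbol = g, study_id = paste0("s", i),
               log2fc = runif(40, -2, 2), p_value = runif(40, 0, 0.049))
  })
  names(perStudy) <- paste0("s", 1:5)
  tal <- voteCount(perStudy, minStudies = 2)

  # oracle: nested loops over genes and studies
  for (g in genes) {
    signs <- c()
    for (s in names(perStudy)) {
      hit <- perStudy[[s]]$gene_symbol == g
      if (any(hit)) signs <- c(signs, sign(perStudy[[s]]$log2fc[hit][1]))
    }
    inTally <- g %in% tal$gene_symbol
    expect_identical(inTally, length(signs) >= 2, label = g)
    if (inTally) {
      row <- tal[tal$gene_symbol == g, ]
      expect_equal(row$n_studies_present, length(signs))
      expect_identical(row$concordant, length(unique(signs)) == 1L)
    }
  }

  # multi-analyte studies contribute one sign (largest |log2fc| wins)
  dup <- list(
    s1 = data.frame(gene_symbol = c("A", "A"), study_id = "s1",
                    log2fc = c(0.7, -2.0), p_value = c(0.01, 0.01)),
    s2 = data.frame(gene_symbol = "A", study_id = "s2",
                    log2fc = -1, p_value = 0.01))
  t2 <- voteCount(dup)
  expect_equal(t2$n_studies_present, 2L)
  expect_true(t2$concordant)  # -2 wins in s1, agrees with s2
})

test_that("concordance and coverage filters behave as set operations", {
  tal <- data.frame(gene_symbol = c("up", "down", "mixed"),
                    n_studies_present = c(3L, 2L, 2L),
                    signs = I(list(c(1, 1, 1), c(-1, -1), c(1, -1))),
                    concordant = c(TRUE, TRUE, FALSE))
  expect_setequal(concordantDirection(tal)$gene_symbol, c("up", "down"))

  m1 <- toyMatrix(matrix(1:4, 2, dimnames = list(c("up", "down"), 1:2)))
  m2 <- toyMatrix(matrix(1:4, 2, dimnames = list(c("up", "x"), 1:2)))
  expect_identical(coverageFilter(c("up", "down"), list(m1, m2)), "up")
  expect_error(coverageFilter("up", list()), "at least one")

  # fully concordant simulated studies retain every shared marker
  shared <- data.frame(gene_symbol = sprintf("SH%02d", 1:8),
                       effect = rep(c(1.2, -1.2), 4))
  cfgs <- lapply(1:3, function(i)
    simStudyConfig(paste0("c", i), n_case = 40, n_control = 40,
                   noise_sd = 0.3, missing_beta = c(1, 99), seed = i))
  bl <- simulateMultiStudy(cfgs, shared, concordance = 1)
  disc <- suppressWarnings(runDiscovery(bl))
  expect_true(all(shared$gene_symbol %in% disc$concordant$gene_symbol))
})

test_that("funnel stage sizes never grow", {
  shared <- data.frame(gene_symbol = sprintf("SH%02d", 1:10),
                       effect = rep(c(1, -1), 5))
  cfgs <- lapply(1:4, function(i)
    simStudyConfig(paste0("c", i), study_specific_hits = 5, seed = i + 50))
  bl <- simulateMultiStudy(cfgs, shared, concordance = 0.7, seed = 2)
  disc <- suppressWarnings(
    runDiscovery(bl, validationMatrices = list(bl[[1]]$matrix)))
  cnt <- disc$counts
  expect_true(cnt["daps"] <= cnt["unique_proteins"])
  expect_true(cnt["shared"] <= cnt["daps"])
  expect_true(cnt["concordant"] <= cnt["shared"])
  expect_true(cnt["covered"] <= cnt["concordant"])
})

test_that("down-selection recovers informative proteins and ignores noise", {
  hits <- vapply(1:20, function(s) {
    b <- plantedCohort(seed = s + 100, nPerArm = 80, effect = 1.5,
                       nMarkers = 3, nNoise = 20, noise = 1.0)
    sig <- downSelectPanel(
      c(sprintf("MARK%02d", 1:3), "PROT0001", "PROT0002"),
      b$matrix, b$subjects$group, repeats = 10, seed = s)
    setequal(geneSymbols(sig), sprintf("MARK%02d", 1:3))
  }, logical(1))
  expect_gte(sum(hits), 18)

  # a constant (uninformative) protein never changes the selection
  b <- plantedCohort(seed = 77, nMarkers = 2, nNoise = 10)
  base <- downSelectPanel(c("MARK01", "MARK02", "PROT0003"),
                          b$matrix, b$subjects$group, repeats = 3, seed = 1)
  vals <- rbind(abundance(b$matrix),
                FLAT = rep(0, ncol(b$matrix)))
  m2 <- CohortMatrix(vals, "planted", scale = "zscore")
  withFlat <- downSelectPanel(c("MARK01", "MARK02", "PROT0003", "FLAT"),
                              m2, b$subjects$group, repeats = 3, seed = 1)
  expect_identical(geneSymbols(base), setdiff(geneSymbols(withFlat), "FLAT"))

  # single candidate: returned as-is
  one <- downSelectPanel("MARK01", b$matrix, b$subjects$group)
  expect_identical(geneSymbols(one), "MARK01")
})
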