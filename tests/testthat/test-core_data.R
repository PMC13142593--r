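test_that("matrix I/O round-trips identifiers, values and missingness", {
  vals <- matrix(c(1.25, NA, 3.5, 4.125, 5, 2^0.5 * 1e-3), nrow = 3,
                 dimnames = list(c("NPTX2", "PKM", "YWHAG"), c("s1", "s2")))
  m <- toyMatrix(vals)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeCohortMatrix(m, path)
  m2 <- readCohortMatrix(path, "toy")
  expect_identical(rownames(m2), rownames(m))
  expect_identical(colnames(m2), colnames(m))
  expect_identical(is.na(abundance(m2)), is.na(abundance(m)))
  expect_lt(max(abs(abundance(m2) - abundance(m)), na.rm = TRUE), 1e-9)
})

test_that("reader rejects duplicates and non-numeric cells, collapses analytes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\ts1\ts2\ts3",
               "PKM\t1\t2\t3",
               "PKM\t1\t5\t9",
               "GDA\t2\t2\t2"), path)
  expect_error(readCohortMatrix(path, "c"), "PKM")
  m <- readCohortMatrix(path, "c", collapse = TRUE)
  expect_equal(nrow(m), 2L)
  # highest-variance analyte is kept for the duplicated symbol
  expect_equal(unname(abundance(m)["PKM", ]), c(1, 5, 9))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\ts1", "PKM\toops"), bad)
  expect_error(readCohortMatrix(bad, "c"), "PKM.*s1")
  nas <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_symbol\ts1\ts2", "PKM\tNaN\tna"), nas)
  expect_true(all(is.na(abundance(readCohortMatrix(nas, "c")))))
})

test_that("missingness filter removes strictly above the threshold only", {
  vals <- matrix(rnorm(30), nrow = 3, ncol = 10,
                 dimnames = list(c("none", "eight", "nine"),
                                 paste0("s", 1:10)))
  vals["eight", 1:8] <- NA  # exactly 0.80: retained under strict >
  vals["nine", 1:9] <- NA   # 0.90: removed
  m <- filterMissingness(toyMatrix(vals))
  expect_setequal(rownames(m), c("none", "eight"))
  expect_equal(ncol(m), 10L)
  expect_match(provenance(m)[length(provenance(m))], "nine")
  expect_error(filterMissingness(toyMatrix(vals)[0, ]), "empty")
})

test_that("quantile normalization equalizes column distributions", {
  m <- toyMatrix(matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                        dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  qn <- abundance(quantileNormalize(m))
  expect_equal(unname(qn[, "s1"]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, "s2"]), c(2.5, 3.5, 4.5))

  # identical columns are unchanged
  same <- matrix(c(5, 1, 9, 5, 1, 9), nrow = 3,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(abundance(quantileNormalize(toyMatrix(same))), same)

  # property: all columns share the same sorted multiset (complete data)
  set.seed(42)
  vals <- matrix(rexp(200, 0.1), nrow = 20,
                 dimnames = list(sprintf("p%02d", 1:20),
                                 sprintf("s%02d", 1:10)))
  qn <- abundance(quantileNormalize(toyMatrix(vals)))
  for (j in 2:ncol(qn))
    expect_equal(sort(qn[, j]), sort(qn[, 1]), ignore_attr = TRUE)
  # Kolmogorov distance between any two columns is 0
  expect_equal(suppressWarnings(
    ks.test(qn[, 1], qn[, 5])$statistic), c(D = 0))

  # missing entries are left missing and excluded from the reference
  vals[3, 2] <- NA
  qn2 <- abundance(quantileNormalize(toyMatrix(vals)))
  expect_true(is.na(qn2[3, 2]))
  expect_equal(sum(is.na(qn2)), 1L)

  # agrees with the reference implementation on complete data
  expect_equal(abundance(quantileNormalize(toyMatrix(vals[, -2]))),
               limma::normalizeQuantiles(vals[, -2]), tolerance = 1e-12)
})

test_that("log2 transform validates positivity and flags the offender", {
  m <- toyMatrix(matrix(c(8, 1, 2, 4, 16, 0.5), nrow = 3,
                        dimnames = list(c("a", "b", "c"), c("s1", "s2"))))
  lg <- log2Transform(m)
  expect_equal(unname(abundance(lg)[, 1]), c(3, 0, 1))
  expect_identical(abundanceScale(lg), "log2")
  bad <- toyMatrix(matrix(c(8, 0), 2, 1,
                          dimnames = list(c("a", "zero"), "s1")))
  expect_error(log2Transform(bad), "zero.*s1")
  expect_s4_class(log2Transform(bad, pseudocount = 1), "CohortMatrix")
})

test_that("z-scoring standardizes per protein and is idempotent", {
  vals <- matrix(c(1, 2, 3, 10, 20, 60), nrow = 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  z <- zscoreStandardize(toyMatrix(vals, scale = "log2"))
  expect_equal(unname(abundance(z)["a", ]), c(-1, 0, 1))
  expect_equal(rowMeans(abundance(z)), c(a = 0, b = 0), tolerance = 1e-9)
  expect_equal(apply(abundance(z), 1, sd), c(a = 1, b = 1),
               tolerance = 1e-9)
  z2 <- zscoreStandardize(z)
  expect_equal(abundance(z2), abundance(z), tolerance = 1e-9)
  const <- toyMatrix(matrix(5, 1, 3, dimnames = list("flat", 1:3)),
                     scale = "log2")
  expect_error(zscoreStandardize(const), "flat")
})

test_that("preprocessing pipeline runs in fixed order and logs provenance", {
  set.seed(7)
  vals <- matrix(rlnorm(400, 3, 0.4), nrow = 40,
                 dimnames = list(sprintf("p%02d", 1:40),
                                 sprintf("s%02d", 1:10)))
  vals[1, 1:9] <- NA
  z <- preprocessCohort(toyMatrix(vals))
  expect_identical(abundanceScale(z), "zscore")
  expect_match(paste(provenance(z), collapse = ";"),
               "filterMissingness.*quantileNormalize.*log2Transform.*zscoreStandardize")
  expect_false("p01" %in% rownames(z))
})

test_that("A/T classification is strict, total, and handles missing input", {
  subj <- data.frame(subject_id = c("a", "b", "c", "d"),
                     ptau = c(3.0, 2.3, 1.0, NA),
                     abeta42 = c(100, 100, 100, 100))
  out <- classifyATStatus(subj, adniATRule())
  # 0.030 > 0.023 -> positive; exactly 0.023 -> negative (strict)
  expect_identical(out$amyloid_status, c("pos", "neg", "neg", "unknown"))
  expect_identical(out$tau_status, out$amyloid_status)
  # complete subjects are never unknown
  expect_true(all(out$amyloid_status[1:3] %in% c("pos", "neg")))

  bangs <- data.frame(subject_id = "x", ttau = 10, abeta42 = 100)
  expect_identical(
    classifyATStatus(bangs, bangsATRule())$amyloid_status, "neg")
  zero <- data.frame(subject_id = "z", ptau = 1, abeta42 = 0)
  expect_error(classifyATStatus(zero, adniATRule()), "z")
})

test_that("registry sums reproduce every printed role total", {
  reg <- cohortRegistry()
  totals <- attr(reg, "totals")
  for (i in seq_len(nrow(totals))) {
    role <- totals$role[i]
    for (f in c("n_total", "aneg_tneg", "apos_tpos", "aneg_tneg_cu",
                "apos_tpos_ci", "apos_tpos_mci", "apos_tpos_dem",
                "n_female", "n_male")) {
      printed <- totals[[f]][i]
      if (is.na(printed)) next
      expect_equal(
        suppressMessages(summarizeRegistry(reg, role, f)),
        printed, info = paste(role, f))
    }
  }
  expect_error(summarizeRegistry(reg, "discovery", "bogus"), "unknown field")
})
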