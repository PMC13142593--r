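#' Read a pipeline configuration from YAML
#'
#' A configuration file carries a master \code{seed}, an optional
#' \code{out_dir}, and per-stage parameter blocks; recognized preprocessing
#' keys are \code{max_missing_fraction}, \code{pseudocount} and
#' \code{batch_center}. Unspecified values fall back to the package
#' defaults so a minimal file is valid.
#'
#' @param path YAML file path.
#' @return nested list of configuration blocks with defaults filled in.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    seed = 1L, out_dir = NULL,
    preprocessing = list(max_missing_fraction = 0.8, pseudocount = 0,
                         batch_center = FALSE),
    discovery = list(lfc_threshold = 0.6, p_threshold = 0.05,
                     min_studies = 2, require_concordance = TRUE,
                     epsilon = 0.002),
    evaluation = list(k = 5, repeats = 10, ridge = 1e-3))
  out <- utils::modifyList(defaults, cfg)
  stopifnot(out$preprocessing$max_missing_fraction >= 0,
            out$preprocessing$max_missing_fraction < 1,
            out$discovery$min_studies >= 2)
  out
}

#' Run the full synthetic end-to-end workflow
#'
#' Simulates a multi-study discovery compendium plus training, validation
#' and progression cohorts, runs the discovery funnel, evaluates the
#' selected panel diagnostically (repeated CV and frozen external
#' validation) and prognostically (median split, covariate-adjusted Cox,
#' Kaplan-Meier), and runs a protein-clinical association pass -- each
#' stage seeded deterministically from the master seed via [deriveSeed()].
#' Re-running with the same seed reproduces every artifact exactly.
#'
#' @param seed master seed.
#' @param nStudies number of discovery studies (default 8).
#' @param nShared number of truly shared dysregulated proteins.
#' @param effect absolute planted effect size, log2 units.
#' @param noiseSd residual noise, log2 units.
#' @param nPerArm subjects per arm in each discovery study.
#' @param outDir optional directory; when given, matrices, results and a
#'   JSON manifest with file checksums are written there.
#' @return list with elements \code{discovery}, \code{diagnostics},
#'   \code{prognosis}, \code{association} and (if written) \code{manifest}.
#' @export
runPipeline <- function(seed = 1, nStudies = 8, nShared = 20, effect = 1,
                        noiseSd = 0.4, nPerArm = 30, outDir = NULL) {
  shared <- data.frame(
    gene_symbol = sprintf("BIO%03d", seq_len(nShared)),
    effect = effect * rep(c(1, -1), length.out = nShared))
  cfgs <- lapply(seq_len(nStudies), function(i)
    simStudyConfig(sprintf("study%02d", i), n_case = nPerArm,
                   n_control = nPerArm, noise_sd = noiseSd,
                   study_specific_hits = 5,
                   seed = deriveSeed(seed, paste0("sim", i))))
  bundles <- simulateMultiStudy(cfgs, shared, concordance = 1,
                                seed = deriveSeed(seed, "flips"))

  mkCohort <- function(id, s) {
    b <- simulateCohort(simStudyConfig(id, n_case = 60, n_control = 60,
                                       planted_markers = shared,
                                       noise_sd = noiseSd,
                                       seed = deriveSeed(seed, s)))
    b$matrix <- zscoreStandardize(b$matrix)
    b
  }
  train <- mkCohort("train", "train")
  valid <- mkCohort("valid", "valid")

  disc <- runDiscovery(bundles,
                       validationMatrices = list(train$matrix, valid$matrix),
                       train = list(matrix = train$matrix,
                                    labels = train$subjects$group),
                       seed = deriveSeed(seed, "discover"))

  cvRes <- repeatedCvAuc(valid$matrix, valid$subjects$group,
                         disc$signature, seed = deriveSeed(seed, "cv"),
                         comparison = "A+T+ vs A-T-")
  model <- fitPanelModel(train$matrix, train$subjects$group,
                         disc$signature)
  extRes <- externalValidation(model, valid$matrix, valid$subjects$group,
                               comparison = "A+T+ vs A-T-")

  prog <- simulateProgressionCohort(simProgressionConfig(
    n_subjects = 300, hazard_ratio_true = 3, baseline_hazard = 0.08,
    seed = deriveSeed(seed, "progression")))
  hz <- coxFit(prog, label = "CU_to_ATMCI")
  km <- kaplanMeier(prog)

  clin <- .withSeed(deriveSeed(seed, "clinical"), {
    sc <- scoreSubjects(model, valid$matrix)
    data.frame(subject_id = colnames(valid$matrix),
               age = valid$subjects$age, sex = valid$subjects$sex,
               cognition = 25 - 4 * sc / stats::sd(sc) +
                 stats::rnorm(ncol(valid$matrix), 0, 2))
  })
  assoc <- clinicalAssociation(valid$matrix[geneSymbols(disc$signature), ],
                               clin, variables = "cognition")

  result <- list(discovery = disc,
                 diagnostics = list(cv = cvRes, external = extRes,
                                    model = model),
                 prognosis = list(hazard = hz, km = km),
                 association = assoc)

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      signature = {
        p <- file.path(outDir, "signature.json")
        jsonlite::write_json(list(name = signatureName(disc$signature),
                                  genes = geneSymbols(disc$signature)),
                             p, auto_unbox = TRUE)
        p
      },
      diagnostics = {
        p <- file.path(outDir, "diagnostics.tsv")
        common <- intersect(names(cvRes), names(extRes))
        utils::write.table(rbind(cvRes[, common], extRes[, common]),
                           p, sep = "\t", row.names = FALSE, quote = FALSE)
        p
      },
      hazard = {
        p <- file.path(outDir, "hazard.tsv")
        utils::write.table(hz, p, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        p
      },
      km = {
        p <- file.path(outDir, "km.tsv")
        utils::write.table(km, p, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        p
      },
      association = {
        p <- file.path(outDir, "association.tsv")
        utils::write.table(assoc, p, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        p
      })
    manifest <- data.frame(
      artifact = names(paths), path = unname(paths),
      md5 = vapply(paths, function(p) unname(tools::md5sum(p)),
                   character(1)),
      stringsAsFactors = FALSE)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"))
    result$manifest <- manifest
  }
  result
}
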