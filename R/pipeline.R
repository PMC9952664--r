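#' Run the full simulation-to-prediction pipeline
#'
#' End-to-end driver over synthetic two-breed data: simulate genotypes and a
#' trait, invert and re-apply the 100-kg standardisation (so the adjustment
#' stage runs on realistic raw measurements), per-breed genotype QC,
#' per-breed mixed-model GWAS on the chip (and on the dense panel when
#' simulated), cross-breed inverse-variance meta-analysis, per-breed BayesC
#' window-variance GWAS, pooling of significant variants, and per-breed
#' cross-validated genomic prediction with the CHIP, SIG and TK models
#' (plus IMPUTED when a dense panel exists).
#'
#' Every stage draws its randomness from a sub-seed of `seed`, so the same
#' configuration and seed reproduce the report exactly.
#'
#' @param params a [simParams()] configuration.
#' @param seed global pipeline seed (defaults to `params$seed`).
#' @param bayes a [bayesCConfig()]; the default shortens the chain to
#'   demo scale (3000 iterations, 1500 burn-in).
#' @param nReps,nFolds cross-validation scheme (demo default 3 x 5).
#' @param pcs number of GRM principal components used as GWAS covariates.
#' @param models subset of c("CHIP", "IMPUTED", "SIG", "TK") to evaluate.
#' @param includeMeta include meta-analysis hits in the selection panel.
#' @param outDir optional output directory for report, GWAS tables and a
#'   JSON manifest.
#' @return list of class `PipelineResult`: `report` (breed x model mean/SD
#'   accuracy table), `gwas` (per-breed association tables), `meta`,
#'   `windows`, `panel`, `h2` (per-breed REML estimates), `manifest`.
#' @export
runPipeline <- function(params, seed = params$seed,
                        bayes = bayesCConfig(nIter = 3000, nBurnin = 1500,
                                             thin = 5),
                        nReps = 3, nFolds = 5, pcs = 5,
                        models = c("CHIP", "SIG", "TK"),
                        includeMeta = TRUE, outDir = NULL) {
  stopifnot(inherits(params, "SimParams"))
  params$seed <- as.integer(seed)
  hasDense <- params$nSnpsDense > 0

  ## 1) simulate genotypes and trait ------------------------------------
  geno <- simulateGenotypes(params)
  chip <- if (hasDense) geno[, which(snpMap(geno)$on_chip)] else geno
  sim <- simulatePhenotypes(geno, params)
  ph <- sim$phenotypes

  ## 2) raw measurements and 100-kg standardisation ---------------------
  adjIn <- data.frame(sample_id = ph$sample_id,
                      sex_class = ifelse(ph$sex == "M", "sire", "dam"),
                      bft100_mm = ph$phenotype,
                      age100_days = 160)
  raw <- simulateRawMeasurements(adjIn, seed = stageSeed(seed, "raw"))
  adj <- adjustPhenotypes(raw)
  y <- adj$bft100_mm                       # equals the simulated trait
  breeds <- sort(unique(ph$breed))

  gwasTabs <- list(); hitsByBreed <- list(); winByBreed <- list()
  ilByBreed <- list(); h2ByBreed <- list(); qcByBreed <- list()
  denseQcByBreed <- list()

  for (b in breeds) {
    idx <- which(ph$breed == b)
    gb <- chip[idx, ]
    qc <- qcFilter(gb)
    qcByBreed[[b]] <- qc
    grm <- buildGRM(qc$genotypes)
    pca <- pcaCovariates(grm, k = min(pcs, nSamples(qc$genotypes) - 1))
    W <- cbind(1, ph$sex[idx] == "M", ph$age_days[idx], pca$eigenvectors)
    null <- fitMlmNull(y[idx], W, grm)
    assoc <- testSnps(null, qc$genotypes)
    th <- bonferroniThresholds(nrow(assoc))
    hits <- extractHits(assoc, th)
    gwasTabs[[b]] <- assoc
    hitsByBreed[[b]] <- hits$significant

    bc <- bayes
    bc$seed <- stageSeed(seed, paste0("bayesc_", b))
    fit <- runBayesC(y[idx], W, qc$genotypes, bc)
    win <- windowGV(fit, qc$genotypes)
    winByBreed[[b]] <- significantWindows(win, bayes$gvThresholdPercent)

    if (hasDense) {
      qcd <- qcFilter(geno[idx, ], hweP = 1e-6)
      denseQcByBreed[[b]] <- qcd
      grmD <- buildGRM(qcd$genotypes)
      pcaD <- pcaCovariates(grmD, k = min(pcs, nSamples(qcd$genotypes) - 1))
      WD <- cbind(1, ph$sex[idx] == "M", ph$age_days[idx], pcaD$eigenvectors)
      nullD <- fitMlmNull(y[idx], WD, grmD)
      assocD <- testSnps(nullD, qcd$genotypes)
      thD <- bonferroniThresholds(nrow(assocD))
      ilByBreed[[b]] <- extractHits(assocD, thD)$significant
    }
  }

  ## 3) cross-breed meta-analysis ---------------------------------------
  metaTab <- NULL; metaSig <- NULL
  if (length(breeds) >= 2) {
    studies <- lapply(breeds, function(b) {
      a <- gwasTabs[[b]]
      data.frame(snp_id = a$snp_id, effect_allele = a$effect_allele,
                 other_allele = snpMap(chip)$allele_ref[
                   match(a$snp_id, snpMap(chip)$snp_id)],
                 beta = a$beta, se = a$se, p_value = a$p_value,
                 stringsAsFactors = FALSE)
    })
    studies <- lapply(studies, function(s) s[!is.na(s$beta) & s$se > 0, ])
    metaTab <- inverseVarianceMeta(harmonizeAlleles(studies))
    mh <- metaHits(metaTab, mTests = nrow(gwasTabs[[breeds[1]]]))
    metaSig <- mh$significant
  }

  ## 4) pool significant variants ---------------------------------------
  clAll <- do.call(rbind, hitsByBreed)
  ilAll <- if (length(ilByBreed)) do.call(rbind, ilByBreed) else NULL
  winAll <- do.call(rbind, winByBreed)
  panel <- tryCatch(
    buildSigPanel(clHits = clAll, ilHits = ilAll,
                  metaHitsDf = if (includeMeta) metaSig else NULL,
                  cbWindows = winAll, snpMap = snpMap(chip)),
    error = function(e) NULL)

  ## 5) cross-validated prediction per breed ----------------------------
  reportRows <- list(); cvDetail <- list()
  for (b in breeds) {
    idx <- which(ph$breed == b)
    gb <- qcByBreed[[b]]$genotypes
    Wb <- cbind(1, ph$sex[idx] == "M", ph$age_days[idx])
    vcFull <- remlVarComp(y[idx], Wb, list(buildGRM(gb)))
    h2b <- min(max(vcFull$h2Hat, 1e-3), 1)
    h2ByBreed[[b]] <- h2b
    panelIds <- if (is.null(panel)) character(0) else
      panel$snp_id[panel$on_panel]
    for (m in models) {
      if (m %in% c("SIG", "TK") &&
          length(intersect(panelIds, snpMap(gb)$snp_id)) == 0) next
      gUse <- gb
      if (m == "IMPUTED") {
        if (!hasDense) next
        gUse <- denseQcByBreed[[b]]$genotypes
      }
      cv <- crossValidate(gUse, y[idx], Wb, model = m, panel = panelIds,
                          nReps = nReps, nFolds = nFolds,
                          seed = stageSeed(seed, paste0("cv_", b, "_", m)),
                          h2 = h2b)
      cvDetail[[paste(b, m, sep = "_")]] <- cv
      reportRows[[length(reportRows) + 1]] <- data.frame(
        breed = b, model = m, mean_gpa = cv$meanGpa, sd_gpa = cv$sdGpa,
        h2 = h2b, stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, reportRows)

  manifest <- list(
    package = "growsel",
    version = as.character(packageVersion("growsel")),
    seed = as.integer(seed),
    sim = unclass(params),
    bayes = unclass(bayes),
    cv = list(nReps = nReps, nFolds = nFolds),
    pcs = pcs, models = models, includeMeta = includeMeta,
    panel_size = if (is.null(panel)) 0L else nrow(panel)
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writePhenoTable(report, file.path(outDir, "report.tsv"))
    for (b in breeds)
      writePhenoTable(gwasTabs[[b]], file.path(outDir, paste0("gwas_", b, ".tsv")))
    if (!is.null(metaTab))
      writePhenoTable(metaTab, file.path(outDir, "meta.tsv"))
    if (!is.null(panel))
      writePhenoTable(as.data.frame(panel), file.path(outDir, "panel.tsv"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA),
               file.path(outDir, "manifest.json"))
  }

  structure(list(report = report, gwas = gwasTabs, meta = metaTab,
                 windows = winByBreed, panel = panel,
                 h2 = unlist(h2ByBreed), cv = cvDetail,
                 manifest = manifest),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult (seed", x$manifest$seed, ")\n")
  if (!is.null(x$panel))
    cat("  selection panel:", nrow(x$panel), "SNPs\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
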