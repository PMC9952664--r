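#' Simulation parameters for two-breed genotype/phenotype data
#'
#' Bundles every knob of the two-breed simulator. Defaults emulate a
#' desk-scale version of a two-breed pig nucleus population genotyped on a
#' chip-density panel: two breeds separated by drift (Balding-Nichols
#' divergence), a sparse-QTL plus polygenic trait architecture, and fixed
#' effects of sex and measurement age.
#'
#' @param nPerBreed integer vector, individuals per breed.
#' @param nSnps number of chip-panel SNPs.
#' @param nSnpsDense optional denser panel size (0 = chip only). When
#'   positive, the simulator generates `nSnpsDense` SNPs and flags an
#'   evenly-spaced subset of `nSnps` of them as the chip panel
#'   (`snpMap$on_chip`), mimicking an imputed panel that contains the chip.
#' @param nChromosomes number of autosomes (pig karyotype: 18).
#' @param chromLengthBp physical length per chromosome in bp.
#' @param nQtl number of causal variants.
#' @param h2 target narrow-sense heritability in \[0,1\].
#' @param fst breed divergence in \[0,1).
#' @param ldRho latent adjacent-marker haplotype correlation in \[0,1).
#'   Haplotypes are a first-order Markov chain: a latent Gaussian AR(1)
#'   process thresholded at the allele frequency, so realized genotype r2
#'   between neighbours is below `ldRho` (0 gives exact independence).
#' @param mafFloor lower clamp on breed allele frequencies; with a positive
#'   floor no generated SNP is monomorphic.
#' @param sexEffect additive fixed effect of male sex on the trait scale.
#' @param ageSlope fixed-effect slope per day of measurement age.
#' @param sexRatioMale probability an individual is male. The default 0.5 is
#'   balanced; real test-station data can be far more imbalanced (a preset of
#'   0.0536, roughly 1 male per 18 females, is typical of sow-line farms).
#' @param ageMeanDays,ageSdDays measurement-age distribution.
#' @param traitMean,traitSd phenotype location and scale.
#' @param qtlEffectDist "normal" (default) or "gamma" (shape 0.4, random
#'   signs) for raw QTL effect draws before joint rescaling to `h2`.
#' @param seed integer RNG seed; one global seed is split into independent
#'   per-stage seeds so stages are individually reproducible.
#' @return A validated list of class `SimParams`.
#' @export
simParams <- function(nPerBreed = c(500, 500), nSnps = 3000, nSnpsDense = 0,
                      nChromosomes = 18, chromLengthBp = 1.25e8,
                      nQtl = 30, h2 = 0.4, fst = 0.1, ldRho = 0.3,
                      mafFloor = 0.01,
                      sexEffect = 0.5, ageSlope = 0.02, sexRatioMale = 0.5,
                      ageMeanDays = 160, ageSdDays = 8,
                      traitMean = 10, traitSd = 2,
                      qtlEffectDist = c("normal", "gamma"), seed = 1L) {
  qtlEffectDist <- match.arg(qtlEffectDist)
  stopifnot(all(nPerBreed >= 1), nSnps >= 1, nChromosomes >= 1,
            chromLengthBp >= 1, nQtl >= 0, ageSdDays >= 0, traitSd > 0)
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (ldRho < 0 || ldRho >= 1) stop("ldRho must lie in [0, 1)")
  if (nQtl > max(nSnps, nSnpsDense)) stop("nQtl cannot exceed the panel size")
  if (nSnps < nChromosomes)
    stop("invalid configuration: fewer SNPs than chromosomes")
  if (nSnpsDense > 0 && nSnpsDense < nSnps)
    stop("nSnpsDense must be >= nSnps (the chip is a subset of the dense panel)")
  structure(list(
    nPerBreed = as.integer(nPerBreed), nSnps = as.integer(nSnps),
    nSnpsDense = as.integer(nSnpsDense),
    nChromosomes = as.integer(nChromosomes), chromLengthBp = chromLengthBp,
    nQtl = as.integer(nQtl), h2 = h2, fst = fst, ldRho = ldRho,
    mafFloor = mafFloor, sexEffect = sexEffect, ageSlope = ageSlope,
    sexRatioMale = sexRatioMale, ageMeanDays = ageMeanDays,
    ageSdDays = ageSdDays, traitMean = traitMean, traitSd = traitSd,
    qtlEffectDist = qtlEffectDist, seed = as.integer(seed)
  ), class = "SimParams")
}

#' @export
print.SimParams <- function(x, ...) {
  cat("SimParams:", paste(x$nPerBreed, collapse = " + "), "individuals,",
      x$nSnps, "chip SNPs",
      if (x$nSnpsDense > 0) sprintf("(%d dense)", x$nSnpsDense) else "",
      "\n  Fst", x$fst, " h2", x$h2, " QTLs", x$nQtl,
      " ldRho", x$ldRho, " seed", x$seed, "\n")
  invisible(x)
}

# Derive an independent, reproducible sub-seed per pipeline stage from the
# single user-facing seed. Kept below 2^31 - 1.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483647)
}

#' Simulate two-breed SNP genotypes
#'
#' Draws ancestral allele frequencies uniform on \[0.05, 0.95\], diverges them
#' per breed with the Balding-Nichols model
#' Beta(p(1-F)/F, (1-p)(1-F)/F), and generates within-breed haplotypes as a
#' first-order Markov chain along each chromosome (latent Gaussian AR(1) with
#' correlation `ldRho`, thresholded at the breed allele frequency). Two
#' haplotypes are summed per individual to dosages in {0,1,2}. SNP positions
#' are evenly spaced with jitter. Deterministic given `params$seed`.
#'
#' Monomorphic columns (possible at small n despite the frequency clamp) are
#' redrawn; the count is available as `attr(x, "n_redrawn")`.
#'
#' @param params a [simParams()] object.
#' @return A [GenotypeData-class] with breed labels in `sampleInfo()$breed`
#'   and, when a dense panel is requested, a logical `on_chip` column in
#'   `snpMap()`.
#' @export
simulateGenotypes <- function(params) {
  stopifnot(inherits(params, "SimParams"))
  set.seed(stageSeed(params$seed, "genotypes"))
  M <- if (params$nSnpsDense > 0) params$nSnpsDense else params$nSnps
  nBreeds <- length(params$nPerBreed)
  nTot <- sum(params$nPerBreed)

  # map: SNPs split as evenly as possible across chromosomes, jittered grid
  chrom <- rep(seq_len(params$nChromosomes), length.out = M)
  chrom <- sort(chrom)
  pos <- integer(M)
  for (c_ in seq_len(params$nChromosomes)) {
    idx <- which(chrom == c_)
    m <- length(idx)
    if (!m) next
    spacing <- params$chromLengthBp / (m + 1)
    p0 <- spacing * seq_len(m) + runif(m, -0.3, 0.3) * spacing
    pos[idx] <- sort(pmax(1L, pmin(as.integer(round(p0)), as.integer(params$chromLengthBp))))
  }
  alleles <- matrix(sample(c("A", "C", "G", "T"), 2 * M, replace = TRUE), ncol = 2)
  same <- alleles[, 1] == alleles[, 2]
  alleles[same, 2] <- ifelse(alleles[same, 1] == "A", "G", "A")

  pAnc <- runif(M, 0.05, 0.95)
  fl <- max(params$mafFloor, 1e-4)
  pBreed <- matrix(0, nBreeds, M)
  for (b in seq_len(nBreeds)) {
    if (params$fst == 0) pBreed[b, ] <- pAnc
    else {
      F <- params$fst
      pBreed[b, ] <- rbeta(M, pAnc * (1 - F) / F, (1 - pAnc) * (1 - F) / F)
    }
    pBreed[b, ] <- pmin(pmax(pBreed[b, ], fl), 1 - fl)
  }

  drawDosages <- function(nInd, pvec) {
    nH <- 2L * nInd
    H <- matrix(0L, nH, M)
    thr <- qnorm(pvec)
    rho <- params$ldRho
    sq <- sqrt(1 - rho^2)
    z <- rnorm(nH)
    H[, 1] <- as.integer(z < thr[1])
    for (j in 2:M) {
      if (chrom[j] != chrom[j - 1]) z <- rnorm(nH)
      else z <- rho * z + sq * rnorm(nH)
      H[, j] <- as.integer(z < thr[j])
    }
    H[seq(1, nH, by = 2), ] + H[seq(2, nH, by = 2), ]
  }

  X <- matrix(0, nTot, M)
  breed <- character(nTot)
  off <- 0L
  for (b in seq_len(nBreeds)) {
    nb <- params$nPerBreed[b]
    X[off + seq_len(nb), ] <- drawDosages(nb, pBreed[b, ])
    breed[off + seq_len(nb)] <- paste0("breed", b)
    off <- off + nb
  }

  # redraw any column that came out monomorphic overall
  nRedrawn <- 0L
  mono <- which(apply(X, 2, function(v) length(unique(v)) == 1L))
  for (j in mono) {
    for (trial in 1:20) {
      col <- unlist(lapply(seq_len(nBreeds), function(b) {
        h <- matrix(as.integer(rnorm(2L * params$nPerBreed[b]) < qnorm(pBreed[b, j])),
                    ncol = 2, byrow = TRUE)
        h[, 1] + h[, 2]
      }))
      if (length(unique(col)) > 1L) { X[, j] <- col; nRedrawn <- nRedrawn + 1L; break }
    }
  }

  snpMap <- data.frame(
    snp_id = sprintf("snp_%d_%d", chrom, pos),
    chrom = chrom, pos_bp = pos,
    allele_ref = alleles[, 1], allele_alt = alleles[, 2],
    stringsAsFactors = FALSE
  )
  # positions can collide after jitter rounding; disambiguate ids
  dup <- duplicated(snpMap$snp_id)
  if (any(dup)) snpMap$snp_id[dup] <- paste0(snpMap$snp_id[dup], "b")
  if (params$nSnpsDense > 0) {
    chipIdx <- unique(as.integer(round(seq(1, M, length.out = params$nSnps))))
    snpMap$on_chip <- seq_len(M) %in% chipIdx
  }
  samples <- data.frame(
    sample_id = sprintf("ind%04d", seq_len(nTot)),
    breed = breed, stringsAsFactors = FALSE
  )
  g <- GenotypeData(X, snpMap, samples)
  attr(g, "n_redrawn") <- nRedrawn
  attr(g, "breed_freqs") <- pBreed
  g
}

#' Simulate an additive quantitative trait on given genotypes
#'
#' Samples `nQtl` causal SNPs, draws raw effects (normal by default), and
#' rescales them jointly so the variance of the true breeding values equals
#' `h2 * traitSd^2`. The phenotype is intercept + sex effect + age slope x
#' (age - mean age) + breeding value + Gaussian residual with variance
#' `(1 - h2) * traitSd^2`.
#'
#' @param genotypes a complete (no missing) [GenotypeData-class].
#' @param params a [simParams()] object.
#' @return list with `phenotypes` (data.frame: sample_id, breed, sex,
#'   age_days, phenotype) and `truth` (class `SimTruth`: qtl_indices,
#'   qtl_effects, true_bv, sigma_g2, sigma_e2, realized_h2).
#' @export
simulatePhenotypes <- function(genotypes, params) {
  stopifnot(is(genotypes, "GenotypeData"), inherits(params, "SimParams"))
  X <- dosages(genotypes)
  if (anyNA(X)) stop("simulatePhenotypes requires complete genotypes")
  n <- nrow(X)
  set.seed(stageSeed(params$seed, "phenotypes"))

  if (params$nQtl == 0L && params$h2 > 0)
    stop("cannot scale to h2 > 0 with zero QTLs")
  qtl <- sort(sample.int(ncol(X), params$nQtl))
  if (params$h2 == 0) {
    eff <- numeric(length(qtl))
    bv <- numeric(n)
    sg2 <- 0
  } else {
    effRaw <- switch(params$qtlEffectDist,
      normal = rnorm(length(qtl)),
      gamma  = rgamma(length(qtl), shape = 0.4, rate = 1) *
               sample(c(-1, 1), length(qtl), replace = TRUE))
    Zq <- scale(X[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
    bvRaw <- drop(Zq %*% effRaw)
    vRaw <- var(bvRaw)
    if (vRaw <= 0) stop("cannot scale: raw breeding-value variance is zero")
    s <- sqrt(params$h2 * params$traitSd^2 / vRaw)
    eff <- effRaw * s
    bv <- bvRaw * s
    sg2 <- var(bv)
  }
  se2 <- (1 - params$h2) * params$traitSd^2
  resid <- if (se2 > 0) rnorm(n, 0, sqrt(se2)) else numeric(n)

  sex <- ifelse(runif(n) < params$sexRatioMale, "M", "F")
  age <- round(rnorm(n, params$ageMeanDays, params$ageSdDays))
  fixedPart <- params$traitMean +
    params$sexEffect * (sex == "M") +
    params$ageSlope * (age - params$ageMeanDays)
  y <- fixedPart + bv + resid

  varNonFixed <- var(bv + resid)
  truth <- structure(list(
    qtl_indices = qtl, qtl_effects = eff, true_bv = bv,
    sigma_g2 = sg2, sigma_e2 = se2,
    realized_h2 = if (varNonFixed > 0) sg2 / varNonFixed else 0
  ), class = "SimTruth")
  stopifnot(truth$realized_h2 >= 0, truth$realized_h2 <= 1)

  ph <- data.frame(
    sample_id = sampleInfo(genotypes)$sample_id,
    breed = if ("breed" %in% names(sampleInfo(genotypes)))
      sampleInfo(genotypes)$breed else NA_character_,
    sex = sex, age_days = age, phenotype = y,
    stringsAsFactors = FALSE
  )
  list(phenotypes = ph, truth = truth)
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", length(x$qtl_indices), "QTLs, sigma_g2 =",
      format(x$sigma_g2, digits = 4), ", sigma_e2 =",
      format(x$sigma_e2, digits = 4), ", realized h2 =",
      format(x$realized_h2, digits = 3), "\n")
  invisible(x)
}

#' Invert the 100-kg standardisation to raw test-station measurements
#'
#' Produces raw measured body weight, age and backfat such that applying the
#' sire/dam 100-kg correction formulas recovers the supplied adjusted values
#' exactly. Measured body weight is drawn from a normal distribution
#' (default mean 115 kg, matching end-of-test weights) truncated above
#' 100 kg so every correction denominator is positive.
#'
#' @param adjusted data.frame with columns `sample_id`, `sex_class`
#'   ("sire"/"dam"), `bft100_mm`, `age100_days` and optionally
#'   `birth_weight_kg`.
#' @param seed RNG seed.
#' @param bwMean,bwSd measured body-weight distribution (kg).
#' @param forceBw optional vector of measured body weights, overriding the
#'   random draw (e.g. 100 to get the identity mapping).
#' @return data.frame with sample_id, sex_class, measured_bw_kg,
#'   measured_age_days, measured_bft_mm, birth_weight_kg.
#' @export
simulateRawMeasurements <- function(adjusted, seed = 1L,
                                    bwMean = 115, bwSd = 7, forceBw = NULL) {
  need <- c("sample_id", "sex_class", "bft100_mm", "age100_days")
  stopifnot(all(need %in% names(adjusted)))
  n <- nrow(adjusted)
  set.seed(stageSeed(seed, "raw_measurements"))
  if (is.null(forceBw)) {
    lo <- 100 + 1e-6
    u <- runif(n, pnorm((lo - bwMean) / bwSd), 1)
    bw <- bwMean + bwSd * qnorm(u)
  } else {
    bw <- rep_len(forceBw, n)
  }
  cons <- adjustmentConstants(adjusted$sex_class)
  mbft <- adjusted$bft100_mm * (cons$A + cons$B * (bw - 100)) / cons$A
  # AGE = age - (bw-100)/CF, CF = cf*bw/age  =>  age = AGE / (1 - (bw-100)/(cf*bw))
  shrink <- 1 - (bw - 100) / (cons$cfMultiplier * bw)
  if (any(shrink <= 0)) stop("measured body weight too extreme to invert age correction")
  mage <- adjusted$age100_days / shrink
  data.frame(
    sample_id = adjusted$sample_id,
    sex_class = adjusted$sex_class,
    measured_bw_kg = bw,
    measured_age_days = mage,
    measured_bft_mm = mbft,
    birth_weight_kg = if ("birth_weight_kg" %in% names(adjusted))
      adjusted$birth_weight_kg else NA_real_,
    stringsAsFactors = FALSE
  )
}
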