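#' Alternate-allele frequency per SNP
#'
#' p_i = (sum of dosages) / (2 x non-missing count).
#'
#' @param x a [GenotypeData-class] or dosage matrix.
#' @return numeric vector of alt-allele frequencies, named by SNP id.
#' @export
alleleFreq <- function(x) {
  m <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  nObs <- colSums(!is.na(m))
  if (any(nObs == 0)) {
    bad <- colnames(m)[nObs == 0]
    if (is.null(bad)) bad <- which(nObs == 0)
    stop("SNP(s) with no called genotypes: ", paste(bad, collapse = ", "))
  }
  colSums(m, na.rm = TRUE) / (2 * nObs)
}

#' Minor allele frequency from alt-allele frequency
#' @param p alt-allele frequency vector.
#' @return pmin(p, 1 - p).
#' @export
mafFromFreq <- function(p) pmin(p, 1 - p)

#' Mean-impute missing dosages
#'
#' Missing calls are replaced by twice the in-sample alt-allele frequency
#' (the column mean), the standard practice for building GRMs and GWAS
#' design matrices. Imputed values are never persisted to disk.
#'
#' @param x [GenotypeData-class] or dosage matrix.
#' @return numeric dosage matrix without missing values.
#' @export
meanImpute <- function(x) {
  m <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  if (!anyNA(m)) return(m)
  p2 <- 2 * alleleFreq(m)
  idx <- which(is.na(m), arr.ind = TRUE)
  m[idx] <- p2[idx[, 2]]
  m
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts no more
#' probable than the observed one. Probabilities are computed by the
#' standard stable recurrence over heterozygote counts.
#'
#' @param nAA,nAa,naa genotype counts (hom ref, het, hom alt).
#' @return exact p-value in (0, 1].
#' @export
hweExactTest <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("need at least one genotype")
  nA <- 2 * nAA + nAa            # copies of the A allele
  nRare <- min(nA, 2 * n - nA)   # rare-allele count
  if (nRare == 0) return(1.0)

  # heterozygote counts share the parity of the rare-allele count
  hetVals <- seq(nRare %% 2, nRare, by = 2)
  probs <- numeric(length(hetVals))
  # anchor the recurrence at the distribution mode (numerically stable),
  # then recurse outward:
  #   P(h-2)/P(h) = h(h-1) / (4(homR+1)(homC+1))
  #   P(h+2)/P(h) = 4 homR homC / ((h+2)(h+1))
  # with homR/homC the rare/common homozygote counts at het = h.
  hExp <- nRare * (2 * n - nRare) / (2 * n)
  i0 <- which.min(abs(hetVals - hExp))
  probs[i0] <- 1
  homAt <- function(h) {
    homR <- (nRare - h) / 2
    c(homR, n - h - homR)
  }
  if (i0 > 1) {
    h <- hetVals[i0]
    for (i in (i0 - 1):1) {
      hm <- homAt(h)
      probs[i] <- probs[i + 1] * h * (h - 1) / (4 * (hm[1] + 1) * (hm[2] + 1))
      h <- h - 2
    }
  }
  if (i0 < length(hetVals)) {
    h <- hetVals[i0]
    for (i in (i0 + 1):length(hetVals)) {
      hm <- homAt(h)
      probs[i] <- probs[i - 1] * 4 * hm[1] * hm[2] / ((h + 2) * (h + 1))
      h <- h + 2
    }
  }
  probs <- probs / sum(probs)
  obsHet <- nAa
  pObs <- probs[match(obsHet, hetVals)]
  if (is.na(pObs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

#' Pairwise composite LD between two SNPs
#'
#' Squared Pearson correlation of dosage vectors on complete-case
#' individuals.
#'
#' @param x [GenotypeData-class] or dosage matrix.
#' @param snpA,snpB column index or snp_id.
#' @return r-squared in \[0, 1\].
#' @export
pairwiseR2 <- function(x, snpA, snpB) {
  m <- if (is(x, "GenotypeData")) dosages(x) else as.matrix(x)
  if (is.character(snpA)) snpA <- match(snpA, colnames(m))
  if (is.character(snpB)) snpB <- match(snpB, colnames(m))
  a <- m[, snpA]; b <- m[, snpB]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (var(a) == 0 || var(b) == 0)
    stop("zero dosage variance on complete-case individuals")
  cor(a, b)^2
}

#' Quality-control filter for a genotype panel
#'
#' Filters are applied in a fixed, documented order:
#' 1. drop SNPs that are unmapped or on a sex chromosome (non-autosomal);
#' 2. drop individuals with more than `sampleMissing` missing genotypes;
#' 3. drop SNPs with call rate strictly below `callRate`;
#' 4. drop SNPs with minor allele frequency strictly below `maf`;
#' 5. optionally drop SNPs with exact Hardy-Weinberg p strictly below `hweP`
#'    (used for dense/imputed panels).
#'
#' Boundary semantics follow the printed rules: "less than" removes, so a
#' SNP at exactly the MAF or call-rate threshold is retained.
#'
#' @param genotypes a [GenotypeData-class].
#' @param callRate minimum SNP call rate retained (default 0.95).
#' @param maf minimum minor-allele frequency retained (default 0.01).
#' @param sampleMissing maximum individual missingness retained (default 0.05).
#' @param hweP optional Hardy-Weinberg exact-test p-value floor (e.g. 1e-6);
#'   `NULL` disables the test.
#' @param autosomes chromosome labels accepted as autosomal; default accepts
#'   any strictly positive integer label and removes "X", "Y", "MT", "0",
#'   and unmapped (`NA`) SNPs.
#' @return list with `genotypes` (filtered [GenotypeData-class]) and
#'   `report` (a `QcReport` data.frame of per-rule removal counts).
#' @export
qcFilter <- function(genotypes, callRate = 0.95, maf = 0.01,
                     sampleMissing = 0.05, hweP = NULL, autosomes = NULL) {
  stopifnot(is(genotypes, "GenotypeData"))
  g <- genotypes
  nSnp0 <- nSnps(g); nInd0 <- nSamples(g)
  rules <- character(); removedSnps <- integer(); removedInds <- integer()

  note <- function(rule, snps = 0L, inds = 0L) {
    rules <<- c(rules, rule)
    removedSnps <<- c(removedSnps, as.integer(snps))
    removedInds <<- c(removedInds, as.integer(inds))
  }

  chrom <- snpMap(g)$chrom
  if (is.null(autosomes)) {
    chromInt <- suppressWarnings(as.integer(as.character(chrom)))
    keep <- !is.na(chromInt) & chromInt >= 1
  } else {
    keep <- as.character(chrom) %in% as.character(autosomes)
  }
  note("unmapped_or_sex_chrom", snps = sum(!keep))
  g <- g[, which(keep)]

  missRate <- rowMeans(is.na(dosages(g)))
  keepInd <- missRate <= sampleMissing          # "more than 5%" removed
  note("sample_missingness", inds = sum(!keepInd))
  g <- g[which(keepInd), ]
  if (nSamples(g) == 0) stop("no individuals left after QC")

  cr <- colMeans(!is.na(dosages(g)))
  keep <- cr >= callRate                        # "less than 95%" removed
  note("snp_call_rate", snps = sum(!keep))
  g <- g[, which(keep)]
  if (nSnps(g) == 0) stop("no SNPs left after QC")

  p <- alleleFreq(g)
  keep <- mafFromFreq(p) >= maf                 # "less than 1%" removed
  note("maf", snps = sum(!keep))
  g <- g[, which(keep)]
  if (nSnps(g) == 0) stop("no SNPs left after QC")

  if (!is.null(hweP)) {
    d <- dosages(g)
    pv <- vapply(seq_len(ncol(d)), function(j) {
      v <- d[, j]
      hweExactTest(sum(v == 0, na.rm = TRUE), sum(v == 1, na.rm = TRUE),
                   sum(v == 2, na.rm = TRUE))
    }, numeric(1))
    keep <- pv >= hweP
    note("hwe", snps = sum(!keep))
    g <- g[, which(keep)]
    if (nSnps(g) == 0) stop("no SNPs left after QC")
  }

  report <- data.frame(rule = rules, snps_removed = removedSnps,
                       individuals_removed = removedInds,
                       stringsAsFactors = FALSE)
  attr(report, "input") <- c(snps = nSnp0, individuals = nInd0)
  attr(report, "retained") <- c(snps = nSnps(g), individuals = nSamples(g))
  stopifnot(sum(report$snps_removed) + nSnps(g) == nSnp0,
            sum(report$individuals_removed) + nSamples(g) == nInd0)
  list(genotypes = g, report = report)
}

#' Principal components of a genomic relationship matrix
#'
#' Top-k eigenvectors of the GRM, the covariates used to correct GWAS
#' models for population stratification. Variance explained is the
#' eigenvalue as a percentage of the GRM trace.
#'
#' @param grm a [GRM-class].
#' @param k number of components (default 5).
#' @return list of class `PcaResult`: `eigenvectors` (n x k, orthonormal),
#'   `eigenvalues` (length k, descending), `varianceExplainedPercent`.
#' @export
pcaCovariates <- function(grm, k = 5) {
  stopifnot(is(grm, "GRM"), k >= 1)
  G <- grmMatrix(grm)
  n <- nrow(G)
  if (k > n) stop("k cannot exceed the number of individuals")
  e <- eigen(G, symmetric = TRUE)
  structure(list(
    eigenvectors = e$vectors[, seq_len(k), drop = FALSE],
    eigenvalues = e$values[seq_len(k)],
    varianceExplainedPercent = 100 * e$values[seq_len(k)] / sum(diag(G))
  ), class = "PcaResult")
}

#' @export
print.PcaResult <- function(x, ...) {
  cat("PcaResult:", ncol(x$eigenvectors), "components;",
      "variance explained (%):",
      paste(sprintf("%.2f", x$varianceExplainedPercent), collapse = ", "), "\n")
  invisible(x)
}
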