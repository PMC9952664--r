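# Independent oracles and small fixture builders used across the suite.

# Exact HWE test by full enumeration: multinomial probability of every
# heterozygote count conditional on the allele counts, via log-factorials.
hweEnumOracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nB <- 2 * n - nA
  if (min(nA, nB) == 0) return(1.0)
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(nA + 1) + lgamma(nB + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  pObs <- p[match(nAa, hets)]
  sum(p[p <= pObs * (1 + 1e-12)])
}

# Hudson-style Fst estimator (ratio of averages) from two dosage matrices.
hudsonFst <- function(x1, x2) {
  p1 <- colMeans(x1) / 2; p2 <- colMeans(x2) / 2
  n1 <- 2 * nrow(x1); n2 <- 2 * nrow(x2)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  keep <- den > 0
  sum(num[keep]) / sum(den[keep])
}

# SNP-BLUP / ridge-regression oracle for GBLUP equivalence: Henderson
# mixed-model equations on marker effects (intercept unpenalised, markers
# ridged at lambda = sigmaE2 / (sigmaG2 / den)), GEBV = Z bhat.
ridgeGebvOracle <- function(X, y, trainIdx, sigmaG2, sigmaE2) {
  p <- colMeans(X[trainIdx, , drop = FALSE]) / 2
  den <- 2 * sum(p * (1 - p))
  Z <- sweep(X, 2, 2 * p, "-")
  Zt <- Z[trainIdx, , drop = FALSE]
  M <- ncol(Z)
  lam <- sigmaE2 / (sigmaG2 / den)
  A <- cbind(1, Zt)
  lhs <- crossprod(A) + diag(c(0, rep(lam, M)))
  sol <- solve(lhs, crossprod(A, y[trainIdx]))
  drop(Z %*% sol[-1])
}

# Expected BayesC model size on pure-noise data, by direct Monte-Carlo
# integration of the posterior inclusion probability q*BF/(1 + q*BF) with
# r ~ N(0, cjj*sigmaE2) — independent of the Gibbs implementation. The
# saturation of the inclusion probability at 1 puts this value below the
# naive prior expectation M*(1 - pi0).
expectedModelSizeOracle <- function(cjj, sigmaB2, sigmaE2, pi0, nDraw = 4e5) {
  q <- (1 - pi0) / pi0
  sum(vapply(cjj, function(c_) {
    r <- rnorm(nDraw, 0, sqrt(c_ * sigmaE2))
    v0 <- c_ * sigmaE2
    v1 <- c_^2 * sigmaB2 + c_ * sigmaE2
    logBF <- 0.5 * (log(v0) - log(v1)) + 0.5 * r^2 * (1 / v0 - 1 / v1)
    mean(q * exp(logBF) / (1 + q * exp(logBF)))
  }, numeric(1)))
}

# Small deterministic genotype object built by hand.
makeTinyGeno <- function(d, chrom = NULL, pos = NULL) {
  d <- as.matrix(d)
  M <- ncol(d)
  if (is.null(chrom)) chrom <- rep(1L, M)
  if (is.null(pos)) pos <- seq_len(M) * 1000L
  map <- data.frame(snp_id = paste0("s", seq_len(M)), chrom = chrom,
                    pos_bp = pos,
                    allele_ref = rep("A", M), allele_alt = rep("G", M),
                    stringsAsFactors = FALSE)
  smp <- data.frame(sample_id = paste0("i", seq_len(nrow(d))),
                    stringsAsFactors = FALSE)
  GenotypeData(d, map, smp)
}

# One-breed simulated dataset used by several tests.
simOneBreed <- function(n, m, nQtl, h2, seed, ldRho = 0.2, nChrom = 5) {
  p <- simParams(nPerBreed = n, nSnps = m, nChromosomes = nChrom,
                 nQtl = nQtl, h2 = h2, fst = 0, ldRho = ldRho, seed = seed)
  g <- simulateGenotypes(p)
  sim <- simulatePhenotypes(g, p)
  list(geno = g, pheno = sim$phenotypes, truth = sim$truth, params = p)
}
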