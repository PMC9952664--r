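test_that("chains are deterministic given the seed", {
  s <- simOneBreed(n = 120, m = 150, nQtl = 3, h2 = 0.4, seed = 61)
  W <- matrix(1, 120, 1)
  cfg <- bayesCConfig(nIter = 400, nBurnin = 200, thin = 2, seed = 5,
                      priorSigmaG2 = 1.6, priorSigmaE2 = 2.4)
  f1 <- runBayesC(s$pheno$phenotype, W, s$geno, cfg)
  f2 <- runBayesC(s$pheno$phenotype, W, s$geno, cfg)
  expect_identical(f1$postMeanBeta, f2$postMeanBeta)
  expect_identical(f1$samples$sigmaE2, f2$samples$sigmaE2)
})

test_that("under pure noise the model size stays near the prior expectation", {
  set.seed(71)
  n <- 500; M <- 2000
  d <- matrix(rbinom(n * M, 2, 0.3), n, M)
  g <- makeTinyGeno(d, chrom = rep(1:4, each = M / 4),
                    pos = rep(seq_len(M / 4) * 5e4, 4))
  y <- rnorm(n)
  cfg <- bayesCConfig(nIter = 3000, nBurnin = 1500, thin = 5, seed = 9,
                      priorSigmaG2 = 0.5, priorSigmaE2 = 1)
  fit <- runBayesC(y, matrix(1, n, 1), g, cfg)
  # order of magnitude of the prior anchor: about one SNP in a thousand
  expect_gt(fit$meanModelSize, M * 0.001 / 4)
  expect_lt(fit$meanModelSize, M * 0.001 * 4)
  # saturation-aware oracle: direct integration of q*BF/(1+q*BF) at the
  # chain's posterior variance components
  set.seed(72)
  Xc <- scale(d, scale = FALSE)
  oracle <- expectedModelSizeOracle(colSums(Xc[, seq(1, M, by = 40)]^2),
                                    median(fit$samples$sigmaB2),
                                    median(fit$samples$sigmaE2), 0.999) *
    40   # thinned SNP subset scaled back up
  expect_lt(abs(fit$meanModelSize - oracle) / oracle, 0.5)
  expect_true(all(fit$pip >= 0 & fit$pip <= 1))
})

test_that("a large single QTL is found with high inclusion probability", {
  set.seed(81)
  n <- 1000; M <- 500
  d <- matrix(rbinom(n * M, 2, 0.4), n, M)
  g <- makeTinyGeno(d, chrom = rep(1:2, each = M / 2),
                    pos = rep(seq_len(M / 2) * 1e4, 2))
  qtl <- 137
  gvar <- var(d[, qtl])
  bEff <- sqrt(0.3 / (0.7 * gvar))       # QTL explains 30% of phenotypic var
  y <- d[, qtl] * bEff + rnorm(n)
  cfg <- bayesCConfig(nIter = 2000, nBurnin = 1000, thin = 5, seed = 3,
                      priorSigmaG2 = var(y) * 0.3, priorSigmaE2 = var(y) * 0.7)
  fit <- runBayesC(y, matrix(1, n, 1), g, cfg)
  expect_gt(fit$pip[qtl], 0.8)
  expect_equal(unname(which.max(fit$pip)), qtl)
})

test_that("a constant phenotype triggers the variance floor without error", {
  g <- makeTinyGeno(matrix(rbinom(50 * 60, 2, 0.4), 50, 60))
  cfg <- bayesCConfig(nIter = 300, nBurnin = 150, seed = 2,
                      priorSigmaG2 = 0.1, priorSigmaE2 = 0.1)
  fit <- runBayesC(rep(3.2, 50), matrix(1, 50, 1), g, cfg)
  expect_lt(fit$meanModelSize, 5)
  expect_true(is.finite(fit$postSigmaE2))
})

test_that("with every SNP in the model the posterior mean tracks ridge/SNP-BLUP", {
  set.seed(91)
  n <- 500; M <- 1000
  d <- matrix(rbinom(n * M, 2, 0.35), n, M)
  g <- makeTinyGeno(d, chrom = rep(1:4, each = M / 4),
                    pos = rep(seq_len(M / 4) * 1e4, 4))
  p <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * p, "-")
  bTrue <- rnorm(M, 0, sqrt(0.5 / M))
  y <- drop(Z %*% bTrue) + rnorm(n, 0, sqrt(0.5))
  sg2 <- var(drop(Z %*% bTrue)); se2 <- 0.5
  # enormous prior degrees of freedom pin both variances, so the sampler
  # runs at a fixed, matched variance ratio (the ridge limit)
  cfg <- bayesCConfig(piZero = 0, nIter = 1500, nBurnin = 500, thin = 2,
                      seed = 4, priorSigmaG2 = sg2, priorSigmaE2 = se2,
                      dfEffect = 1e6, dfResid = 1e6)
  fit <- runBayesC(y, matrix(1, n, 1), g, cfg)
  lam <- fit$postSigmaE2 / fit$postSigmaB2
  ridge <- drop(solve(crossprod(Z) + diag(lam, M), crossprod(Z, y - mean(y))))
  expect_gt(cor(fit$postMeanBeta, ridge), 0.98)
})

test_that("window variance shares are computed per iteration and zero for silent windows", {
  # hand-built fit: 2 windows, effects only in the first
  d <- matrix(rbinom(40 * 6, 2, 0.5), 40, 6)
  g <- makeTinyGeno(d, chrom = rep(1, 6),
                    pos = c(1e5, 5e5, 9e5, 1.1e6, 1.5e6, 1.9e6))
  B <- rbind(c(0.5, 0, 0.2, 0, 0, 0),
             c(0.1, 0.3, 0, 0, 0, 0))
  fit <- structure(list(samples = list(beta = B),
                        config = bayesCConfig(nIter = 2, nBurnin = 0, seed = 1)),
                   class = "BayesCFit")
  wv <- windowGV(fit, g, windowBp = 1e6)
  expect_equal(nrow(wv), 2)
  w1 <- wv[wv$start_bp == 0, ]
  w2 <- wv[wv$start_bp == 1e6, ]
  expect_equal(w2$gv_percent, 0)
  expect_equal(w1$n_snps, 3)
  expect_equal(w2$n_snps, 3)
  # all genetic variance lives in window 1
  expect_gt(w1$gv_percent, 99.999)

  # oracle: recompute the share for a single iteration directly
  Xc <- scale(d, scale = FALSE)
  g1 <- Xc[, 1:3] %*% B[1, 1:3]
  gt <- Xc %*% B[1, ]
  expect_equal(w1$gv_percent,
               100 * mean(c(var(g1) / var(gt),
                            var(Xc[, 1:3] %*% B[2, 1:3]) /
                              var(Xc %*% B[2, ]))),
               tolerance = 1e-10)
})

test_that("significant windows use a strict threshold, sorted descending", {
  tab <- data.frame(window_id = letters[1:4], chrom = 1, start_bp = 0,
                    end_bp = 1, n_snps = 1,
                    gv_percent = c(0.4, 1.0, 1.01, 7.3))
  sig <- significantWindows(tab, 1.0)
  expect_equal(sig$window_id, c("d", "c"))   # 1.0 itself is excluded
  flat <- data.frame(window_id = as.character(1:200), chrom = 1, start_bp = 0,
                     end_bp = 1, n_snps = 1, gv_percent = rep(100 / 200, 200))
  expect_equal(nrow(significantWindows(flat, 1.0)), 0)
})

test_that("causal windows dominate the genomic-variance partition", {
  recovered <- 0; total <- 0
  for (seed in c(201, 202, 203)) {
    s <- simOneBreed(n = 800, m = 800, nQtl = 8, h2 = 0.5, seed = seed,
                     nChrom = 4)
    W <- cbind(1, s$pheno$sex == "M")
    cfg <- bayesCConfig(nIter = 1500, nBurnin = 750, thin = 5, seed = seed,
                        priorSigmaG2 = s$truth$sigma_g2,
                        priorSigmaE2 = s$truth$sigma_e2)
    fit <- runBayesC(s$pheno$phenotype, W, s$geno, cfg)
    wv <- windowGV(fit, s$geno)
    sig <- significantWindows(wv, 1.0)
    map <- snpMap(s$geno)
    qtlWin <- unique(paste(map$chrom[s$truth$qtl_indices],
                           floor(map$pos_bp[s$truth$qtl_indices] / 1e6),
                           sep = ":"))
    total <- total + length(qtlWin)
    recovered <- recovered + sum(qtlWin %in% sig$window_id)
    # the strongest window contains a causal variant
    expect_true(sig$window_id[1] %in% qtlWin)
  }
  expect_gt(recovered / total, 0.5)
})

test_that("the posterior respects the phenotypic variance decomposition", {
  s <- simOneBreed(n = 800, m = 400, nQtl = 10, h2 = 0.6, seed = 95)
  W <- cbind(1, s$pheno$sex == "M", s$pheno$age_days)
  cfg <- bayesCConfig(nIter = 1500, nBurnin = 750, thin = 5, seed = 8,
                      priorSigmaG2 = s$truth$sigma_g2,
                      priorSigmaE2 = s$truth$sigma_e2)
  fit <- runBayesC(s$pheno$phenotype, W, s$geno, cfg)
  Xc <- scale(meanImpute(s$geno), scale = FALSE)
  ghat <- drop(Xc %*% fit$postMeanBeta)
  expect_lt(abs((var(ghat) + fit$postSigmaE2) / var(s$pheno$phenotype) - 1), 0.15)
})
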