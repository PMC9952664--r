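test_that("simulation is deterministic given the seed", {
  p <- simParams(nPerBreed = c(60, 60), nSnps = 200, nChromosomes = 3,
                 nQtl = 5, seed = 11)
  g1 <- simulateGenotypes(p)
  g2 <- simulateGenotypes(p)
  expect_identical(dosages(g1), dosages(g2))
  expect_identical(snpMap(g1), snpMap(g2))
  s1 <- simulatePhenotypes(g1, p)
  s2 <- simulatePhenotypes(g2, p)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$truth$qtl_effects, s2$truth$qtl_effects)
})

test_that("configuration invariants are enforced", {
  expect_error(simParams(h2 = 1.2), "h2")
  expect_error(simParams(fst = 1), "fst")
  expect_error(simParams(nSnps = 5, nChromosomes = 10, nQtl = 1), "fewer SNPs")
  expect_error(simParams(nQtl = 100, nSnps = 50), "nQtl")
  p0 <- simParams(nPerBreed = 80, nSnps = 60, nChromosomes = 2,
                  nQtl = 0, h2 = 0.5, seed = 1)
  g0 <- simulateGenotypes(p0)
  expect_error(simulatePhenotypes(g0, p0), "zero QTLs")
})

test_that("no divergence gives near-identical breed frequencies and ldRho=0 gives independence", {
  p <- simParams(nPerBreed = c(400, 400), nSnps = 800, nChromosomes = 4,
                 fst = 0, ldRho = 0, nQtl = 5, seed = 7)
  g <- simulateGenotypes(p)
  breed <- sampleInfo(g)$breed
  f1 <- alleleFreq(g[breed == "breed1", ])
  f2 <- alleleFreq(g[breed == "breed2", ])
  expect_lt(mean(abs(f1 - f2)), 0.05)

  # adjacent-marker r2 under independence stays at sampling-noise level
  d <- dosages(g)
  map <- snpMap(g)
  adj <- which(diff(map$chrom) == 0)
  r2 <- vapply(adj[1:300], function(j) cor(d[, j], d[, j + 1])^2, numeric(1))
  expect_lt(mean(r2), 0.02)
})

test_that("positive ldRho induces adjacent-marker correlation", {
  p <- simParams(nPerBreed = 400, nSnps = 500, nChromosomes = 2,
                 fst = 0, ldRho = 0.9, nQtl = 5, seed = 8)
  d <- dosages(simulateGenotypes(p))
  r2 <- vapply(seq_len(400), function(j) cor(d[, j], d[, j + 1])^2, numeric(1))
  expect_gt(mean(r2), 0.2)
})

test_that("breed divergence is visible on PC1 and matches the Hudson Fst target", {
  p <- simParams(nPerBreed = c(500, 500), nSnps = 2000, nChromosomes = 5,
                 fst = 0.1, nQtl = 5, seed = 21)
  g <- simulateGenotypes(p)
  breed <- as.integer(factor(sampleInfo(g)$breed))
  # oracle: plain PCA of the centred dosage matrix
  pc1 <- prcomp(dosages(g), center = TRUE, scale. = FALSE, rank. = 1)$x[, 1]
  expect_gt(abs(cor(pc1, breed)), 0.9)

  fstHat <- hudsonFst(dosages(g)[breed == 1, ], dosages(g)[breed == 2, ])
  expect_lt(abs(fstHat - 0.1), 0.03)
})

test_that("realized heritability matches the target and converges with n", {
  s <- simOneBreed(n = 2000, m = 1000, nQtl = 50, h2 = 0.4, seed = 31)
  expect_lt(abs(s$truth$realized_h2 - 0.4), 0.05)
  # realized_h2 is the variance ratio recomputed from the truth record
  resid <- s$pheno$phenotype - 10 - 0.5 * (s$pheno$sex == "M") -
    0.02 * (s$pheno$age_days - 160) - s$truth$true_bv
  expect_equal(s$truth$realized_h2,
               var(s$truth$true_bv) / var(s$truth$true_bv + resid),
               tolerance = 1e-10)
  s5 <- simOneBreed(n = 5000, m = 800, nQtl = 50, h2 = 0.4, seed = 32)
  expect_lt(abs(s5$truth$realized_h2 - 0.4), 0.03)
})

test_that("zero-heritability and noise-free limits behave", {
  p <- simParams(nPerBreed = 200, nSnps = 100, nChromosomes = 2,
                 nQtl = 10, h2 = 0, seed = 3)
  g <- simulateGenotypes(p)
  s <- simulatePhenotypes(g, p)
  expect_identical(unique(s$truth$true_bv), 0)
  expect_identical(s$truth$sigma_g2, 0)

  # single QTL, no residual: dosage classes differ by exactly the effect
  d <- cbind(c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1))
  g1 <- makeTinyGeno(d)
  p1 <- simParams(nPerBreed = 10, nSnps = 1, nChromosomes = 1, nQtl = 1,
                  h2 = 1, seed = 4)
  s1 <- simulatePhenotypes(g1, p1)
  y <- s1$phenotypes$phenotype
  eff <- s1$truth$qtl_effects[1]
  byDos <- tapply(y - ifelse(s1$phenotypes$sex == "M", 0.5, 0) -
                  0.02 * (s1$phenotypes$age_days - 160), d[, 1], mean)
  expect_equal(as.numeric(diff(byDos)), rep(eff, 2), tolerance = 1e-10)
})

test_that("allele frequencies stay polymorphic with a positive MAF floor", {
  p <- simParams(nPerBreed = c(30, 30), nSnps = 300, nChromosomes = 2,
                 fst = 0.25, mafFloor = 0.05, nQtl = 5, seed = 13)
  g <- simulateGenotypes(p)
  f <- alleleFreq(g)
  expect_true(all(f > 0 & f < 1))
})

test_that("raw-measurement simulation inverts the 100-kg standardisation", {
  adjusted <- data.frame(
    sample_id = paste0("a", 1:50),
    sex_class = rep(c("sire", "dam"), 25),
    bft100_mm = runif(50, 6, 20),
    age100_days = runif(50, 140, 190))
  raw <- simulateRawMeasurements(adjusted, seed = 5)
  back <- adjustPhenotypes(raw)
  expect_lt(max(abs(back$bft100_mm - adjusted$bft100_mm)), 1e-9)
  expect_lt(max(abs(back$age100_days - adjusted$age100_days)), 1e-9)

  # identity at 100 kg
  raw100 <- simulateRawMeasurements(adjusted[1, ], forceBw = 100)
  expect_equal(raw100$measured_bft_mm, adjusted$bft100_mm[1], tolerance = 1e-12)

  # determinism
  expect_identical(simulateRawMeasurements(adjusted, seed = 5), raw)
})
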