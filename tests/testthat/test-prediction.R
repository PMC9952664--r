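fixedVc <- function(sg, se) {
  structure(list(sigmaG2 = sg, sigmaE2 = se,
                 h2Hat = sum(sg) / (sum(sg) + se), loglik = NA,
                 converged = TRUE, nIterations = 0L, method = "fixed",
                 trajectory = NULL),
            class = "VarianceComponents")
}

test_that("GBLUP equals the SNP-BLUP/ridge oracle at a matched variance ratio", {
  set.seed(301)
  n <- 150; M <- 300
  d <- matrix(rbinom(n * M, 2, 0.4), n, M)
  g <- makeTinyGeno(d)
  y <- rnorm(n)
  train <- 1:120
  sg <- 0.8; se <- 1.2
  grm <- buildGRM(g, freqs = colMeans(d[train, ]) / 2)
  pred <- predictGebv(fixedVc(sg, se), y, matrix(1, n, 1), list(grm),
                      trainIdx = train, blend = 0)
  oracle <- ridgeGebvOracle(d, y, train, sg, se)
  expect_lt(max(abs(pred$gebv - oracle)) / max(abs(oracle)), 1e-6)
})

test_that("a test individual unrelated to training gets GEBV zero", {
  G <- diag(5); G[5, 1:4] <- 0; G[1:4, 5] <- 0
  vc <- fixedVc(1, 1)
  pred <- predictGebv(vc, c(rnorm(4), 0), matrix(1, 5, 1), list(G),
                      trainIdx = 1:4, blend = 0)
  expect_equal(pred$gebv[5], 0, tolerance = 1e-12)
})

test_that("two-kernel prediction sums its parts and nests the single kernel", {
  set.seed(302)
  n <- 80
  d <- matrix(rbinom(n * 100, 2, 0.35), n, 100)
  g <- makeTinyGeno(d)
  ks <- splitKernels(g, snpMap(g)$snp_id[1:10])
  y <- rnorm(n)
  W <- matrix(1, n, 1)
  vc2 <- fixedVc(c(0.5, 0.7), 1)
  p2 <- predictGebv(vc2, y, W, list(ks$G1, ks$G2), trainIdx = 1:60)
  expect_equal(p2$gebv, p2$gebv1 + p2$gebv2, tolerance = 1e-12)

  # zero variance on kernel 2 reduces exactly to single-kernel GBLUP
  vc0 <- fixedVc(c(0.5, 0), 1)
  p0 <- predictGebv(vc0, y, W, list(ks$G1, ks$G2), trainIdx = 1:60)
  p1 <- predictGebv(fixedVc(0.5, 1), y, W, list(ks$G1), trainIdx = 1:60)
  expect_equal(p0$gebv, p1$gebv, tolerance = 1e-10)
})

test_that("accuracy follows r/sqrt(h2)", {
  # construct vectors with an exact correlation of 0.3
  set.seed(5)
  e1 <- rnorm(50); e1 <- e1 - mean(e1); e1 <- e1 / sqrt(sum(e1^2))
  e2 <- rnorm(50); e2 <- e2 - mean(e2)
  e2 <- e2 - sum(e2 * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  yStar <- 0.3 * e1 + sqrt(1 - 0.09) * e2
  expect_equal(gpa(e1, yStar, h2 = 0.36), 0.5, tolerance = 1e-10)
  # perfect agreement gives 1/sqrt(h2)
  expect_equal(gpa(yStar, yStar, 0.25), 2)
  expect_error(gpa(e1[1:2], yStar[1:2], 0.5))
  expect_warning(gpa(rep(1, 10), rnorm(10), 0.5), "zero variance")
})

test_that("REML drives the genetic variance to the boundary under pure noise", {
  set.seed(303)
  s <- simOneBreed(n = 1000, m = 600, nQtl = 0, h2 = 0, seed = 304)
  W <- cbind(1, s$pheno$sex == "M")
  vc <- remlVarComp(s$pheno$phenotype, W, list(buildGRM(s$geno)))
  expect_lt(vc$h2Hat, 0.05)
})

test_that("AI-REML and the eigen profile agree on a single kernel", {
  s <- simOneBreed(n = 300, m = 300, nQtl = 30, h2 = 0.5, seed = 306)
  W <- cbind(1, s$pheno$sex == "M")
  grm <- buildGRM(s$geno)
  v1 <- remlVarComp(s$pheno$phenotype, W, list(grm), method = "eigen")
  v2 <- remlVarComp(s$pheno$phenotype, W, list(grm), method = "ai")
  expect_lt(abs(v1$sigmaG2 - v2$sigmaG2) / v1$sigmaG2, 1e-4)
  expect_lt(abs(v1$sigmaE2 - v2$sigmaE2) / v1$sigmaE2, 1e-4)
})

test_that("two-kernel REML nests the single-kernel model", {
  s <- simOneBreed(n = 300, m = 400, nQtl = 20, h2 = 0.5, seed = 307)
  y <- s$pheno$phenotype
  W <- cbind(1, s$pheno$sex == "M")
  map <- snpMap(s$geno)
  ks <- splitKernels(s$geno, map$snp_id[s$truth$qtl_indices])
  v1 <- remlVarComp(y, W, list(buildGRM(s$geno)), method = "ai")
  v2 <- remlVarComp(y, W, list(ks$G1, ks$G2), method = "ai")
  expect_gte(v2$loglik, v1$loglik - 1e-4)

  # when the second kernel carries no signal its variance hits the boundary
  noise <- matrix(rbinom(300 * 200, 2, 0.4), 300, 200)
  gAll <- makeTinyGeno(cbind(dosages(s$geno), noise),
                       chrom = c(map$chrom, rep(9, 200)),
                       pos = c(map$pos_bp, seq_len(200) * 1000))
  ks2 <- splitKernels(gAll, seq_len(nSnps(s$geno)))
  v3 <- remlVarComp(y, W, list(ks2$G1, ks2$G2), method = "ai")
  expect_lt(v3$sigmaG2[2], 0.15 * v3$sigmaG2[1])
  expect_lt(abs(v3$sigmaG2[1] - v1$sigmaG2) / v1$sigmaG2, 0.2)
})

test_that("adding a constant to the phenotype leaves GEBVs unchanged", {
  s <- simOneBreed(n = 200, m = 200, nQtl = 10, h2 = 0.4, seed = 308)
  y <- s$pheno$phenotype
  W <- matrix(1, 200, 1)
  grm <- buildGRM(s$geno)
  v1 <- remlVarComp(y, W, list(grm))
  v2 <- remlVarComp(y + 100, W, list(grm))
  p1 <- predictGebv(v1, y, W, list(grm), trainIdx = 1:150)
  p2 <- predictGebv(v2, y + 100, W, list(grm), trainIdx = 1:150)
  expect_equal(p1$gebv, p2$gebv, tolerance = 1e-6)
  expect_equal(attr(p2, "alphaHat")[1] - attr(p1, "alphaHat")[1], 100,
               tolerance = 1e-6)
})

test_that("cross-validation is deterministic, partitions folds, and is null-calibrated", {
  s <- simOneBreed(n = 300, m = 300, nQtl = 15, h2 = 0.4, seed = 309)
  y <- s$pheno$phenotype
  W <- cbind(1, s$pheno$sex == "M")
  cv1 <- crossValidate(s$geno, y, W, model = "CHIP", nReps = 2, nFolds = 5,
                       seed = 7, h2 = 0.4)
  cv2 <- crossValidate(s$geno, y, W, model = "CHIP", nReps = 2, nFolds = 5,
                       seed = 7, h2 = 0.4)
  expect_identical(cv1$folds, cv2$folds)
  # every individual sits in exactly one test fold per replicate
  expect_true(all(apply(cv1$assignments, 2, function(f)
    all(table(f) %in% c(60)))))

  # permuted phenotypes carry no signal; several permutations average out
  # the per-permutation chance association of order 1/sqrt(n)
  nullGpa <- vapply(1:5, function(k) {
    set.seed(10 + k)
    crossValidate(s$geno, sample(y), W, model = "CHIP", nReps = 2,
                  nFolds = 5, seed = 8 + k, h2 = 0.3)$meanGpa
  }, numeric(1))
  expect_lt(abs(mean(nullGpa)), 0.1)
})

test_that("preselected panels feed the SIG and TK models", {
  s <- simOneBreed(n = 250, m = 250, nQtl = 10, h2 = 0.5, seed = 310)
  y <- s$pheno$phenotype
  W <- matrix(1, 250, 1)
  panel <- snpMap(s$geno)$snp_id[s$truth$qtl_indices]
  cvS <- crossValidate(s$geno, y, W, model = "SIG", panel = panel,
                       nReps = 1, nFolds = 5, seed = 3, h2 = 0.5)
  cvT <- crossValidate(s$geno, y, W, model = "TK", panel = panel,
                       nReps = 1, nFolds = 5, seed = 3, h2 = 0.5)
  expect_true(is.finite(cvS$meanGpa) && is.finite(cvT$meanGpa))
  expect_error(crossValidate(s$geno, y, W, model = "SIG"), "selection panel")
  expect_error(crossValidate(s$geno, y, W, model = "SIG",
                             panel = panel, policy = "refit"),
               "selector")
})
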