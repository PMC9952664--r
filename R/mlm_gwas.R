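# Mixed-linear-model association scan.
#
# Model per SNP: y = W a + x b + u + e with u ~ N(0, lambda * tauInv * K)
# and e ~ N(0, tauInv * I). One eigendecomposition of K rotates the model to
# independent errors, after which the variance ratio lambda is profiled out
# of the REML likelihood in O(n) per evaluation and each SNP costs O(n).

# Profiled REML log-likelihood at a given lambda, in the eigenbasis.
# yR, WR: rotated response/covariates; d: kinship eigenvalues.
remlProfile <- function(lambda, yR, WR, d) {
  v <- lambda * d + 1
  w <- 1 / v
  sw <- sqrt(w)
  ys <- yR * sw
  Ws <- WR * sw
  qr. <- qr(Ws)
  res <- qr.resid(qr., ys)
  rss <- sum(res^2)
  n <- length(yR); c <- ncol(WR)
  df <- n - c
  R <- qr.R(qr.)
  ldWVW <- 2 * sum(log(abs(diag(R))))
  ll <- 0.5 * (df * log(df / (2 * pi)) - df - df * log(rss) -
               sum(log(v)) - ldWVW)
  list(ll = ll, rss = rss, sigmaE2 = rss / df)
}

#' Fit the null mixed model for a GWAS scan
#'
#' Maximises the REML likelihood over the variance ratio lambda (random
#' effect to residual) on a 100-point grid of log10(lambda) in \[-5, 5\]
#' followed by Brent refinement in the bracketing interval.
#'
#' @param y numeric response (standardised phenotype).
#' @param W covariate matrix including the intercept (typically sex,
#'   measurement age and the top GRM eigenvectors).
#' @param grm a [GRM-class], or `NULL` when `eig` is given.
#' @param eig optional precomputed [eigenGRM()] result.
#' @return `MlmNullFit` list: `lambda`, `sigmaE2` (the residual variance
#'   tau^-1), `loglikReml`, cached rotation (`yRot`, `WRot`, eigenvalues
#'   `d`, eigenvectors `U`).
#' @export
fitMlmNull <- function(y, W, grm = NULL, eig = NULL) {
  W <- as.matrix(W)
  stopifnot(length(y) == nrow(W))
  if (qr(W)$rank < ncol(W)) stop("covariate matrix W is rank-deficient")
  if (is.null(eig)) {
    stopifnot(is(grm, "GRM"))
    eig <- eigenGRM(grm)
  }
  U <- eig$vectors
  d <- eig$values
  yR <- drop(crossprod(U, y))
  WR <- crossprod(U, W)

  grid <- 10^seq(-5, 5, length.out = 100)
  lls <- vapply(grid, function(l) remlProfile(l, yR, WR, d)$ll, numeric(1))
  if (!all(is.finite(lls))) stop("non-finite REML likelihood on lambda grid")
  i <- which.max(lls)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(ll10) remlProfile(10^ll10, yR, WR, d)$ll,
                  lower = log10(lo), upper = log10(hi),
                  maximum = TRUE, tol = 1e-6)
  lambda <- 10^opt$maximum
  # honour a boundary solution at effectively zero genetic variance
  if (i == 1 && lls[1] >= opt$objective) lambda <- grid[1]
  prof <- remlProfile(lambda, yR, WR, d)
  structure(list(
    lambda = lambda, sigmaE2 = prof$sigmaE2, loglikReml = prof$ll,
    yRot = yR, WRot = WR, d = d, U = U,
    n = length(y), nCovar = ncol(W)
  ), class = "MlmNullFit")
}

#' @export
print.MlmNullFit <- function(x, ...) {
  cat(sprintf("MlmNullFit: lambda = %.4g, sigmaE2 = %.4g, h2-like ratio = %.3f\n",
              x$lambda, x$sigmaE2, x$lambda / (1 + x$lambda)))
  invisible(x)
}

#' Single-SNP association tests under the fitted mixed model
#'
#' Generalised least squares of the rotated response on rotated
#' \[covariates, SNP\] at the null variance ratio (the fast approximation,
#' default) or with per-SNP re-optimisation of lambda (`mode = "exact"`).
#' Missing dosages are mean-imputed. SNPs collinear with the covariates are
#' emitted with `NA` statistics and `flag = "collinear"`.
#'
#' @param nullFit a [fitMlmNull()] result.
#' @param genotypes a [GenotypeData-class] aligned with the fit's
#'   individuals.
#' @param mode `"approx"` reuses the null lambda for every SNP;
#'   `"exact"` re-optimises lambda per SNP.
#' @return data.frame with columns snp_id, chrom, position, effect_allele,
#'   beta, se, wald_stat, p_value, maf, n_used, flag.
#' @export
testSnps <- function(nullFit, genotypes, mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  stopifnot(inherits(nullFit, "MlmNullFit"), is(genotypes, "GenotypeData"))
  stopifnot(nSamples(genotypes) == nullFit$n)
  Xraw <- dosages(genotypes)
  nUsed <- colSums(!is.na(Xraw))
  X <- meanImpute(genotypes)
  p <- colMeans(X) / 2
  XR <- crossprod(nullFit$U, X)
  map <- snpMap(genotypes)
  n <- nullFit$n; c <- nullFit$nCovar

  scanAt <- function(lambda, cols = NULL) {
    v <- lambda * nullFit$d + 1
    sw <- sqrt(1 / v)
    ys <- nullFit$yRot * sw
    Ws <- nullFit$WRot * sw
    Xs <- (if (is.null(cols)) XR else XR[, cols, drop = FALSE]) * sw
    qr. <- qr(Ws)
    ey <- qr.resid(qr., ys)
    EX <- qr.resid(qr., Xs)
    xx <- colSums(EX^2)
    xy <- drop(crossprod(EX, ey))
    list(xx = xx, xy = xy, rss0 = sum(ey^2))
  }

  if (mode == "approx") {
    s <- scanAt(nullFit$lambda)
    xx <- s$xx; xy <- s$xy; rss0 <- s$rss0
    beta <- xy / xx
    rss <- pmax(rss0 - beta * xy, 0)
    sigma2 <- rss / (n - c - 1)
    se <- sqrt(sigma2 / xx)
  } else {
    m <- ncol(X)
    beta <- se <- numeric(m)
    yFull <- drop(nullFit$U %*% nullFit$yRot)
    WFull <- nullFit$U %*% nullFit$WRot
    eig <- list(values = nullFit$d, vectors = nullFit$U)
    for (j in seq_len(m)) {
      fitj <- fitMlmNull(yFull, cbind(WFull, X[, j]), eig = eig)
      s <- scanAt(fitj$lambda, cols = j)
      beta[j] <- s$xy / s$xx
      rssj <- max(s$rss0 - beta[j] * s$xy, 0)
      se[j] <- sqrt(rssj / (n - c - 1) / s$xx)
    }
    xx <- scanAt(nullFit$lambda)$xx
  }

  collinear <- !is.finite(xx) | xx <= max(xx, na.rm = TRUE) * 1e-12
  beta[collinear] <- NA_real_
  se[collinear] <- NA_real_
  wald <- (beta / se)^2
  pval <- pchisq(wald, df = 1, lower.tail = FALSE)

  data.frame(
    snp_id = map$snp_id, chrom = map$chrom, position = map$pos_bp,
    effect_allele = map$allele_alt,
    beta = beta, se = se, wald_stat = wald, p_value = pval,
    maf = mafFromFreq(p), n_used = nUsed,
    flag = ifelse(collinear, "collinear", ""),
    stringsAsFactors = FALSE
  )
}

#' Bonferroni genome-wide and suggestive thresholds
#'
#' Genome-wide threshold alpha/M and suggestive threshold 1/M for M tests.
#'
#' @param mTests number of tests M.
#' @param alpha family-wise error rate (default 0.05).
#' @return list of class `ThresholdPair`: `genomeWide`, `suggestive`,
#'   `mTests`.
#' @export
bonferroniThresholds <- function(mTests, alpha = 0.05) {
  stopifnot(mTests >= 1, alpha > 0, alpha < 1)
  structure(list(genomeWide = alpha / mTests, suggestive = 1 / mTests,
                 mTests = mTests), class = "ThresholdPair")
}

#' Partition association records by significance thresholds
#'
#' `significant` holds records with p strictly below the genome-wide
#' threshold; `suggestive` holds the remaining records strictly below the
#' suggestive threshold.
#'
#' @param records data.frame with a `p_value` column.
#' @param thresholds a [bonferroniThresholds()] result.
#' @return list with data.frames `significant` and `suggestive`.
#' @export
extractHits <- function(records, thresholds) {
  stopifnot(inherits(thresholds, "ThresholdPair"), nrow(records) >= 1)
  p <- records$p_value
  ok <- !is.na(p)
  sig <- ok & p < thresholds$genomeWide
  sug <- ok & !sig & p < thresholds$suggestive
  list(significant = records[sig, , drop = FALSE],
       suggestive = records[sug, , drop = FALSE])
}

#' Genomic-control inflation factor
#'
#' lambda_GC = median observed chi-square(1) statistic divided by the median
#' of the chi-square(1) distribution (0.4549...).
#'
#' @param records data.frame with `p_value` (or a numeric p-value vector).
#' @return lambda_GC.
#' @export
qqLambda <- function(records) {
  p <- if (is.data.frame(records)) records$p_value else records
  p <- p[!is.na(p)]
  stopifnot(length(p) >= 1)
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}
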