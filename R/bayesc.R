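#' Configuration for the BayesC window-variance GWAS
#'
#' Defaults mirror a chip-scale production analysis: prior probability of a
#' zero SNP effect 0.999 (about one SNP per thousand in the model per
#' iteration), 50,000 Gibbs iterations with 40,000 burn-in, thinning 10, and
#' 1-Mb genomic windows declared significant above 1 percent of genomic
#' variance. Test- and demo-scale runs shorten the chain.
#'
#' @param piZero prior probability a SNP has zero effect, in \[0, 1).
#' @param nIter,nBurnin,thin Gibbs chain control; `nBurnin < nIter`.
#' @param windowBp window width in bp for variance partitioning.
#' @param gvThresholdPercent significance threshold on window %GV.
#' @param priorSigmaG2,priorSigmaE2 starting/prior genetic and residual
#'   variances; when `NULL` they are estimated by the package's own
#'   single-kernel REML on a VanRaden GRM of the same genotypes.
#' @param dfEffect,dfResid prior degrees of freedom of the
#'   scaled-inverse-chi-square priors.
#' @param seed RNG seed for the chain.
#' @return list of class `BayesCConfig`.
#' @export
bayesCConfig <- function(piZero = 0.999, nIter = 50000, nBurnin = 40000,
                         thin = 10, windowBp = 1e6, gvThresholdPercent = 1,
                         priorSigmaG2 = NULL, priorSigmaE2 = NULL,
                         dfEffect = 4, dfResid = 4, seed = 1L) {
  stopifnot(piZero >= 0, piZero < 1, nBurnin < nIter, nBurnin >= 0,
            thin >= 1, windowBp > 0, dfEffect > 2, dfResid > 0)
  structure(list(piZero = piZero, nIter = as.integer(nIter),
                 nBurnin = as.integer(nBurnin), thin = as.integer(thin),
                 windowBp = windowBp, gvThresholdPercent = gvThresholdPercent,
                 priorSigmaG2 = priorSigmaG2, priorSigmaE2 = priorSigmaE2,
                 dfEffect = dfEffect, dfResid = dfResid,
                 seed = as.integer(seed)),
            class = "BayesCConfig")
}

#' Run the BayesC Gibbs sampler
#'
#' Spike-and-slab whole-genome regression: each SNP carries an inclusion
#' indicator with fixed prior probability `1 - piZero` and included effects
#' share one slab variance. Per iteration the sampler updates fixed effects,
#' then each SNP's indicator (effect integrated out) and effect in map
#' order, then the slab and residual variances from their
#' scaled-inverse-chi-square full conditionals. The prior slab scale is
#' derived from the genetic-variance guess via
#' sigma2_beta = sigma2_g / ((1 - piZero) * 2 * sum p(1-p)).
#' Deterministic given `config$seed`.
#'
#' @param y numeric phenotype vector.
#' @param W covariate matrix including intercept.
#' @param genotypes a [GenotypeData-class]; missing dosages are mean-imputed
#'   and columns centred.
#' @param config a [bayesCConfig()].
#' @return list of class `BayesCFit`: `postMeanBeta`, `pip` (posterior
#'   inclusion probabilities), `postSigmaB2`, `postSigmaE2`,
#'   `meanModelSize`, `samples` (thinned post-burn-in draws), `snpMap`,
#'   `config`.
#' @export
runBayesC <- function(y, W, genotypes, config = bayesCConfig()) {
  stopifnot(inherits(config, "BayesCConfig"), is(genotypes, "GenotypeData"))
  W <- as.matrix(W)
  stopifnot(length(y) == nrow(W), length(y) == nSamples(genotypes))
  X <- meanImpute(genotypes)
  p <- colMeans(X) / 2
  Xc <- sweep(X, 2, 2 * p, "-")
  sumpq <- 2 * sum(p * (1 - p))

  sg2 <- config$priorSigmaG2
  se2 <- config$priorSigmaE2
  if (is.null(sg2) || is.null(se2)) {
    if (var(y) == 0) {
      if (is.null(sg2)) sg2 <- 1e-6
      if (is.null(se2)) se2 <- 1e-6
    } else {
      vc <- remlVarComp(y, W, list(buildGRM(genotypes)))
      if (is.null(sg2)) sg2 <- max(vc$sigmaG2, 1e-6 * var(y))
      if (is.null(se2)) se2 <- max(vc$sigmaE2, 1e-6 * var(y))
    }
  }
  piIn <- 1 - config$piZero
  sigmaB2Prior <- if (piIn > 0 && sumpq > 0) sg2 / (piIn * sumpq) else sg2
  # scaled-inv-chisq with E[sigma2] = scale * nu/(nu-2)
  scaleB <- sigmaB2Prior * (config$dfEffect - 2) / config$dfEffect
  scaleE <- se2 * max(config$dfResid - 2, 1) / config$dfResid

  set.seed(config$seed)
  res <- bayesc_gibbs(Xc, y, W, config$piZero,
                      config$nIter, config$nBurnin, config$thin,
                      config$dfEffect, scaleB, config$dfResid, scaleE,
                      sigmaB2Prior, se2)
  structure(list(
    postMeanBeta = setNames(drop(res$postMeanBeta), snpMap(genotypes)$snp_id),
    pip = setNames(drop(res$pip), snpMap(genotypes)$snp_id),
    postSigmaB2 = mean(res$sigmaB2),
    postSigmaE2 = mean(res$sigmaE2),
    meanModelSize = mean(res$modelSize),
    samples = list(beta = res$betaSamples, alpha = res$alphaSamples,
                   sigmaB2 = res$sigmaB2, sigmaE2 = res$sigmaE2,
                   modelSize = res$modelSize),
    snpMap = snpMap(genotypes), config = config
  ), class = "BayesCFit")
}

#' @export
print.BayesCFit <- function(x, ...) {
  cat(sprintf(
    "BayesCFit: %d SNPs, mean model size %.2f, post sigmaE2 %.4g, pi0 %.4g\n",
    length(x$postMeanBeta), x$meanModelSize, x$postSigmaE2, x$config$piZero))
  invisible(x)
}

#' Partition posterior genomic variance into fixed physical windows
#'
#' Windows tile each chromosome in consecutive `windowBp` bins
#' (half-open \[k*windowBp, (k+1)*windowBp)). For every retained iteration
#' the genomic value of window w is g_w = X_w beta_w across individuals and
#' its share is Var(g_w)/Var(sum_w g_w); `gv_percent` is 100 times the
#' posterior mean of shares (default) or the ratio of posterior means
#' (`estimand = "ratio_of_means"`). Iterations with zero total genomic
#' variance are skipped and counted in `attr(, "n_skipped")`.
#'
#' @param fit a [runBayesC()] result.
#' @param genotypes the [GenotypeData-class] used for the fit.
#' @param windowBp window width (default from the fit's config).
#' @param estimand "mean_of_shares" or "ratio_of_means".
#' @return data.frame: window_id, chrom, start_bp, end_bp, n_snps,
#'   gv_percent.
#' @export
windowGV <- function(fit, genotypes, windowBp = NULL,
                     estimand = c("mean_of_shares", "ratio_of_means")) {
  estimand <- match.arg(estimand)
  stopifnot(inherits(fit, "BayesCFit"), is(genotypes, "GenotypeData"))
  if (is.null(windowBp)) windowBp <- fit$config$windowBp
  map <- snpMap(genotypes)
  X <- meanImpute(genotypes)
  Xc <- sweep(X, 2, colMeans(X), "-")
  B <- fit$samples$beta                      # S x M
  S <- nrow(B)

  win <- floor(map$pos_bp / windowBp)
  key <- paste(map$chrom, win, sep = ":")
  uk <- unique(key[order(map$chrom, map$pos_bp)])

  gTot <- Xc %*% t(B)                        # n x S
  vTot <- apply(gTot, 2, var)
  valid <- vTot > 0
  nSkip <- sum(!valid)

  rows <- lapply(uk, function(k) {
    idx <- which(key == k)
    gw <- Xc[, idx, drop = FALSE] %*% t(B[, idx, drop = FALSE])
    vw <- apply(gw, 2, var)
    gv <- if (!any(valid)) 0 else if (estimand == "mean_of_shares")
      100 * mean(vw[valid] / vTot[valid]) else
      100 * mean(vw[valid]) / mean(vTot[valid])
    data.frame(
      window_id = k,
      chrom = map$chrom[idx[1]],
      start_bp = win[idx[1]] * windowBp,
      end_bp = (win[idx[1]] + 1) * windowBp,
      n_snps = length(idx),
      gv_percent = max(gv, 0),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_skipped") <- nSkip
  attr(out, "n_samples") <- S
  out
}

#' Windows exceeding the genomic-variance significance threshold
#'
#' @param results a [windowGV()] table.
#' @param threshold percent of genomic variance; strictly greater windows
#'   are significant (default 1).
#' @return subset of `results`, sorted by descending gv_percent.
#' @export
significantWindows <- function(results, threshold = 1.0) {
  sig <- results[results$gv_percent > threshold, , drop = FALSE]
  sig[order(-sig$gv_percent), , drop = FALSE]
}
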