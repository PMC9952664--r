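# REML variance components and GBLUP prediction with one or two genomic
# kernels, and replicated cross-validation of prediction accuracy.

kernelMatrix <- function(k) if (is(k, "GRM")) grmMatrix(k) else as.matrix(k)

#' REML variance components for one or two genomic kernels
#'
#' Single-kernel fits use the exact eigen-rotated profile likelihood (one
#' eigendecomposition, Brent search over the variance ratio). Multi-kernel
#' fits use average-information REML with EM fallback steps whenever the AI
#' update would leave the parameter space; convergence when
#' max |delta log theta| < `tol` or `maxit` iterations. Non-convergence is
#' flagged (with the parameter trajectory attached), not thrown.
#'
#' @param y numeric response.
#' @param W covariate matrix with intercept.
#' @param kernels list of one or more [GRM-class] objects (or plain
#'   symmetric matrices).
#' @param method "auto" (eigen profile for one kernel, AI-REML otherwise),
#'   "eigen" or "ai".
#' @param maxit,tol iteration control for AI-REML.
#' @return list of class `VarianceComponents`: `sigmaG2` (vector, one per
#'   kernel), `sigmaE2`, `h2Hat`, `loglik`, `converged`, `nIterations`,
#'   `method`, `trajectory`.
#' @export
remlVarComp <- function(y, W, kernels, method = c("auto", "eigen", "ai"),
                        maxit = 100, tol = 1e-8) {
  method <- match.arg(method)
  if (is(kernels, "GRM") || (is.matrix(kernels))) kernels <- list(kernels)
  K <- length(kernels)
  W <- as.matrix(W)
  n <- length(y)
  stopifnot(nrow(W) == n, K >= 1)
  if (qr(W)$rank < ncol(W)) stop("covariate matrix W is rank-deficient")
  Gs <- lapply(kernels, kernelMatrix)
  stopifnot(all(vapply(Gs, nrow, 0L) == n))

  if (method == "auto") method <- if (K == 1) "eigen" else "ai"
  if (method == "eigen") {
    if (K != 1) stop("eigen profile REML supports exactly one kernel")
    fit <- fitMlmNull(y, W, eig = eigenGRM(Gs[[1]]))
    sg <- fit$lambda * fit$sigmaE2
    out <- list(sigmaG2 = sg, sigmaE2 = fit$sigmaE2,
                h2Hat = sg / (sg + fit$sigmaE2),
                loglik = fit$loglikReml, converged = TRUE,
                nIterations = 1L, method = "eigen-profile",
                trajectory = NULL)
    class(out) <- "VarianceComponents"
    return(out)
  }

  vy <- var(y)
  if (vy <= 0) stop("response has zero variance")
  floorV <- 1e-8 * vy
  comps <- c(Gs, list(diag(n)))
  nc <- K + 1
  theta <- c(rep(0.5 * vy / K, K), 0.5 * vy)
  traj <- matrix(NA_real_, maxit, nc)
  converged <- FALSE
  ll <- NA_real_
  it <- 0L
  for (it in seq_len(maxit)) {
    V <- matrix(0, n, n)
    for (i in seq_len(nc)) V <- V + theta[i] * comps[[i]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) stop("covariance matrix not positive definite during AI-REML")
    Vinv <- chol2inv(ch)
    VW <- Vinv %*% W
    WtVW <- crossprod(W, VW)
    P <- Vinv - VW %*% solve(WtVW, t(VW))
    Py <- drop(P %*% y)
    ll <- -0.5 * (2 * sum(log(diag(ch))) +
                  determinant(WtVW, logarithm = TRUE)$modulus +
                  sum(y * Py))

    APy <- lapply(comps, function(A) drop(A %*% Py))
    score <- numeric(nc)
    AI <- matrix(0, nc, nc)
    for (i in seq_len(nc)) {
      trPA <- sum(P * comps[[i]])
      score[i] <- -0.5 * (trPA - sum(Py * APy[[i]]))
      for (j in i:nc) {
        AI[i, j] <- AI[j, i] <- 0.5 * sum(APy[[i]] * (P %*% APy[[j]]))
      }
    }
    delta <- tryCatch(solve(AI, score), error = function(e) NULL)
    newTheta <- if (is.null(delta)) rep(-1, nc) else theta + delta
    if (any(!is.finite(newTheta)) || any(newTheta < floorV)) {
      # EM fallback keeps the parameters in the admissible region
      for (i in seq_len(nc)) {
        trPA <- sum(P * comps[[i]])
        newTheta[i] <- theta[i] + theta[i]^2 * (sum(Py * APy[[i]]) - trPA) / n
      }
      newTheta <- pmax(newTheta, floorV)
    }
    traj[it, ] <- newTheta
    dl <- max(abs(log(pmax(newTheta, floorV)) - log(pmax(theta, floorV))))
    theta <- newTheta
    if (dl < tol) { converged <- TRUE; break }
  }
  out <- list(sigmaG2 = theta[seq_len(K)], sigmaE2 = theta[nc],
              h2Hat = sum(theta[seq_len(K)]) / sum(theta),
              loglik = as.numeric(ll), converged = converged,
              nIterations = it, method = "ai-reml",
              trajectory = traj[seq_len(it), , drop = FALSE])
  class(out) <- "VarianceComponents"
  out
}

#' @export
print.VarianceComponents <- function(x, ...) {
  cat("VarianceComponents (", x$method, "): sigmaG2 = ",
      paste(format(x$sigmaG2, digits = 4), collapse = ", "),
      ", sigmaE2 = ", format(x$sigmaE2, digits = 4),
      ", h2 = ", format(x$h2Hat, digits = 3),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' Predict genomic breeding values from a fitted variance model
#'
#' Computes GEBVs through the BLUP identity
#' g_k = sigma2_gk * G_k\[, train\] V^-1 (y - W alpha_hat) with
#' V = sum_k sigma2_gk G_k\[train, train\] + sigma2_e I, which is valid even
#' when a kernel is singular (small preselected panels). In two-kernel mode
#' GEBV = GEBV_1 + GEBV_2 exactly. Kernels can be blended with the identity
#' ((1-blend) G + blend I) for numerical stability before solving.
#'
#' @param vc a [remlVarComp()] fit obtained on the training individuals.
#' @param y full-length response (only training entries are used).
#' @param W full covariate matrix.
#' @param kernels list of kernels spanning train and test individuals.
#' @param trainIdx indices of training (phenotyped) individuals.
#' @param blend identity blending weight in \[0, 1\) (0 disables).
#' @return data.frame with gebv (and gebv1/gebv2 for two kernels) for every
#'   individual; the fixed-effect estimates are in `attr(, "alphaHat")`.
#' @export
predictGebv <- function(vc, y, W, kernels, trainIdx, blend = 0) {
  stopifnot(inherits(vc, "VarianceComponents"))
  if (is(kernels, "GRM") || is.matrix(kernels)) kernels <- list(kernels)
  K <- length(kernels)
  stopifnot(length(vc$sigmaG2) == K)
  W <- as.matrix(W)
  n <- nrow(W)
  Gs <- lapply(kernels, function(k) {
    G <- kernelMatrix(k)
    if (blend > 0) (1 - blend) * G + blend * diag(nrow(G)) else G
  })
  tr <- trainIdx
  nt <- length(tr)
  V <- diag(vc$sigmaE2, nt)
  for (k in seq_len(K)) V <- V + vc$sigmaG2[k] * Gs[[k]][tr, tr]
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular training covariance matrix (condition estimate ",
         format(kappa(V), digits = 3), ")"))
  Vinv <- chol2inv(ch)
  Wt <- W[tr, , drop = FALSE]
  VinvW <- Vinv %*% Wt
  alphaHat <- solve(crossprod(Wt, VinvW), crossprod(VinvW, y[tr]))
  r <- drop(Vinv %*% (y[tr] - Wt %*% alphaHat))
  parts <- lapply(seq_len(K), function(k)
    vc$sigmaG2[k] * drop(Gs[[k]][, tr, drop = FALSE] %*% r))
  gebv <- Reduce(`+`, parts)
  out <- data.frame(gebv = gebv)
  if (K == 2) { out$gebv1 <- parts[[1]]; out$gebv2 <- parts[[2]] }
  attr(out, "alphaHat") <- drop(alphaHat)
  out
}

#' Genomic prediction accuracy
#'
#' GPA = r(GEBV, y*) / sqrt(h2), where y* is the phenotype corrected by the
#' fixed effects and h2 the (full-data) heritability of the trait. Returns
#' `NA` with a warning when either vector has zero variance.
#'
#' @param gebv predicted breeding values of the evaluation individuals.
#' @param yStar fixed-effect-corrected phenotypes of the same individuals.
#' @param h2 trait heritability in (0, 1\].
#' @return scalar accuracy.
#' @export
gpa <- function(gebv, yStar, h2) {
  stopifnot(length(gebv) == length(yStar), length(gebv) >= 3,
            h2 > 0, h2 <= 1)
  if (var(gebv) == 0 || var(yStar) == 0) {
    warning("zero variance in GEBV or corrected phenotype; accuracy undefined")
    return(NA_real_)
  }
  cor(gebv, yStar) / sqrt(h2)
}

#' Replicated k-fold cross-validation of genomic prediction
#'
#' For each replicate a fresh random partition into `nFolds` folds is
#' drawn; per fold the variance components are re-estimated on the training
#' individuals, GEBVs are predicted for the masked fold, phenotypes are
#' corrected by the training-fold fixed-effect estimates, and accuracy is
#' r(GEBV, y*)/sqrt(h2). The summary is the mean and SD over all fold-level
#' accuracies. `h2` defaults to the full-data single-kernel REML estimate
#' on the supplied panel, held fixed across folds and models.
#'
#' Model tags: `CHIP`/`IMPUTED` use a single kernel of all supplied SNPs
#' (pass the chip or the dense panel as `genotypes`); `SIG` a single kernel
#' of the selection panel; `TK` two kernels (panel, remainder).
#'
#' Selection policy: `"global"` uses `panel` as given (a full-data
#' preselection, the protocol that yields the reported gains but leaks test
#' information into selection); `"refit"` calls `selector(genotypes, y, W,
#' trainIdx)` inside every fold to re-select leakage-free.
#'
#' @param genotypes [GenotypeData-class] of the marker panel.
#' @param y phenotype vector.
#' @param W covariate matrix with intercept.
#' @param model "CHIP", "IMPUTED", "SIG" or "TK".
#' @param panel snp_id vector of the selection panel (SIG/TK, global
#'   policy).
#' @param nReps,nFolds cross-validation scheme (defaults 20 x 5).
#' @param seed scheme seed; folds are reproducible given it.
#' @param h2 heritability for the accuracy denominator (default: full-data
#'   REML on `genotypes`).
#' @param policy "global" or "refit".
#' @param selector function used under the refit policy.
#' @param blend kernel-identity blending passed to [predictGebv()].
#' @return list of class `CvResult`: `folds` (replicate, fold, r, gpa),
#'   `meanGpa`, `sdGpa`, `meanR`, `h2`, `model`, `nReps`, `nFolds`, `seed`.
#' @export
crossValidate <- function(genotypes, y, W, model = c("CHIP", "IMPUTED", "SIG", "TK"),
                          panel = NULL, nReps = 20, nFolds = 5, seed = 1,
                          h2 = NULL, policy = c("global", "refit"),
                          selector = NULL, blend = 0.01) {
  model <- match.arg(model)
  policy <- match.arg(policy)
  stopifnot(is(genotypes, "GenotypeData"))
  W <- as.matrix(W)
  n <- length(y)
  stopifnot(nSamples(genotypes) == n, nrow(W) == n)
  if (model %in% c("SIG", "TK") && policy == "global" && is.null(panel))
    stop("models SIG and TK require a selection panel under the global policy")
  if (policy == "refit" && is.null(selector))
    stop("the refit policy requires a selector function")

  makeKernels <- function(panelIds) {
    switch(model,
      CHIP = , IMPUTED = list(buildGRM(genotypes)),
      SIG = {
        ids <- intersect(panelIds, snpMap(genotypes)$snp_id)
        if (!length(ids)) stop("selection panel shares no SNPs with the genotypes")
        list(buildGRM(genotypes, ids))
      },
      TK = {
        ids <- intersect(panelIds, snpMap(genotypes)$snp_id)
        ks <- splitKernels(genotypes, ids)
        list(ks$G1, ks$G2)
      })
  }
  globalKernels <- if (policy == "global") makeKernels(panel) else NULL

  if (is.null(h2)) {
    vcFull <- remlVarComp(y, W, list(buildGRM(genotypes)))
    h2 <- min(max(vcFull$h2Hat, 1e-3), 1)
  }

  rows <- list()
  assignments <- matrix(NA_integer_, n, nReps)
  for (rep in seq_len(nReps)) {
    set.seed(stageSeed(seed, paste0("cv_rep_", rep)))
    foldOf <- sample(rep(seq_len(nFolds), length.out = n))
    assignments[, rep] <- foldOf
    for (f in seq_len(nFolds)) {
      trainIdx <- which(foldOf != f)
      testIdx <- which(foldOf == f)
      if (length(trainIdx) < 10)
        stop("fewer than 10 training individuals in a fold")
      kernels <- if (policy == "global") globalKernels else
        makeKernels(selector(genotypes, y, W, trainIdx))
      vc <- remlVarComp(y[trainIdx], W[trainIdx, , drop = FALSE],
                        lapply(kernels, function(k) kernelMatrix(k)[trainIdx, trainIdx]))
      pred <- predictGebv(vc, y, W, kernels, trainIdx, blend = blend)
      alpha <- attr(pred, "alphaHat")
      yStar <- y[testIdx] - drop(W[testIdx, , drop = FALSE] %*% alpha)
      gebvTest <- pred$gebv[testIdx]
      r <- if (var(gebvTest) == 0 || var(yStar) == 0) NA_real_ else
        cor(gebvTest, yStar)
      rows[[length(rows) + 1]] <- data.frame(
        replicate = rep, fold = f, r = r,
        gpa = if (is.na(r)) NA_real_ else r / sqrt(h2))
    }
  }
  folds <- do.call(rbind, rows)
  out <- list(folds = folds, assignments = assignments,
              meanGpa = mean(folds$gpa, na.rm = TRUE),
              sdGpa = sd(folds$gpa, na.rm = TRUE),
              meanR = mean(folds$r, na.rm = TRUE),
              h2 = h2, model = model, nReps = nReps, nFolds = nFolds,
              seed = seed, policy = policy)
  class(out) <- "CvResult"
  out
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("CvResult [%s, %s]: %d x %d-fold, GPA = %.3f +/- %.3f (h2 = %.3f)\n",
              x$model, x$policy, x$nReps, x$nFolds, x$meanGpa, x$sdGpa, x$h2))
  invisible(x)
}
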