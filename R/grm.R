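#' Build a VanRaden genomic relationship matrix
#'
#' G = ZZ' / (2 * sum p_i (1 - p_i)) where Z is the dosage matrix centred by
#' twice the alt-allele frequency (VanRaden method 1). Missing dosages are
#' mean-imputed before centring. Frequencies are computed in-sample unless
#' supplied (e.g. training-set frequencies applied to validation animals).
#' No diagonal blending is applied here; prediction code can blend
#' separately for numerical stability.
#'
#' @param genotypes a [GenotypeData-class].
#' @param snpSubset optional SNP selection (indices or snp_id values).
#' @param freqs optional alt-allele frequencies aligned with the subset.
#' @return a [GRM-class].
#' @export
buildGRM <- function(genotypes, snpSubset = NULL, freqs = NULL) {
  stopifnot(is(genotypes, "GenotypeData"))
  g <- if (is.null(snpSubset)) genotypes else genotypes[, snpSubset]
  if (nSnps(g) == 0) stop("empty SNP subset")
  M <- meanImpute(g)
  p <- if (is.null(freqs)) colMeans(M) / 2 else rep_len(freqs, ncol(M))
  den <- 2 * sum(p * (1 - p))
  if (den <= 0)
    stop("zero VanRaden denominator: all subset SNPs are monomorphic")
  Z <- sweep(M, 2, 2 * p, "-")
  G <- tcrossprod(Z) / den
  G <- (G + t(G)) / 2
  new("GRM", matrix = G,
      sampleIds = as.character(sampleInfo(g)$sample_id),
      nSnpsUsed = nSnps(g), denominator = den,
      freqSource = if (is.null(freqs)) "in-sample" else "supplied")
}

#' Split a panel into the two GRMs of two-kernel GBLUP
#'
#' G1 is built from the selected (significant) SNPs, G2 from the remaining
#' panel SNPs; the two sets partition the panel. If one side of the split is
#' empty the call errors unless `allowFallback = TRUE`, in which case a
#' single-kernel GRM of the non-empty side is returned with a warning.
#'
#' @param genotypes a [GenotypeData-class] (the full panel).
#' @param selectedSnps snp_id values (or column indices) of the selected set.
#' @param allowFallback return a single-kernel fallback instead of erroring
#'   on an empty partition.
#' @return list with elements `G1` and `G2` ([GRM-class] or `NULL` under
#'   fallback).
#' @export
splitKernels <- function(genotypes, selectedSnps, allowFallback = FALSE) {
  stopifnot(is(genotypes, "GenotypeData"))
  ids <- snpMap(genotypes)$snp_id
  if (is.numeric(selectedSnps)) selectedSnps <- ids[selectedSnps]
  selectedSnps <- intersect(unique(selectedSnps), ids)
  rest <- setdiff(ids, selectedSnps)
  if (length(selectedSnps) == 0 || length(rest) == 0) {
    if (!allowFallback)
      stop("empty kernel partition; set allowFallback=TRUE for single-kernel fallback")
    warning("empty kernel partition: falling back to a single kernel")
    if (length(selectedSnps) == 0)
      return(list(G1 = NULL, G2 = buildGRM(genotypes)))
    return(list(G1 = buildGRM(genotypes), G2 = NULL))
  }
  list(G1 = buildGRM(genotypes, selectedSnps),
       G2 = buildGRM(genotypes, rest))
}

#' Eigendecompose a genomic relationship matrix
#'
#' Full spectrum in ascending order with reconstruction guaranteed to
#' 1e-8; small negative eigenvalues above -1e-8 (numerical noise of a PSD
#' matrix) are clamped to zero and counted in `attr(, "n_clamped")`.
#'
#' @param grm a [GRM-class] or symmetric matrix.
#' @param tol asymmetry/clamp tolerance.
#' @return list with `values` (ascending) and `vectors`.
#' @export
eigenGRM <- function(grm, tol = 1e-8) {
  G <- if (is(grm, "GRM")) grmMatrix(grm) else as.matrix(grm)
  if (max(abs(G - t(G))) > 1e-8) stop("matrix is not symmetric")
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE]
  nClamp <- sum(vals < 0 & vals > -tol)
  if (any(vals <= -tol))
    warning("eigenvalues below -", format(tol), ": matrix is not PSD")
  vals[vals < 0 & vals > -tol] <- 0
  out <- list(values = vals, vectors = vecs)
  attr(out, "n_clamped") <- nClamp
  out
}
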