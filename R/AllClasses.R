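#' GenotypeData: allele-dosage matrix with marker map and sample metadata
#'
#' Central container for genotypes: an individuals x SNPs matrix of
#' alternate-allele dosages (0/1/2, `NA` for missing), a marker map
#' (`snp_id`, `chrom`, `pos_bp`, `allele_ref`, `allele_alt`) and a sample
#' table (`sample_id` plus arbitrary covariates such as `breed`, `sex`,
#' `age_days`).
#'
#' @slot dosages numeric matrix, individuals x SNPs, values in {0,1,2,NA}.
#' @slot snpMap data.frame with one row per SNP.
#' @slot samples data.frame with one row per individual.
#' @export
setClass("GenotypeData",
  representation(
    dosages = "matrix",
    snpMap  = "data.frame",
    samples = "data.frame"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  d <- object@dosages
  if (ncol(d) != nrow(object@snpMap))
    msg <- c(msg, "ncol(dosages) must equal nrow(snpMap)")
  if (nrow(d) != nrow(object@samples))
    msg <- c(msg, "nrow(dosages) must equal nrow(samples)")
  need <- c("snp_id", "chrom", "pos_bp", "allele_ref", "allele_alt")
  if (!all(need %in% names(object@snpMap)))
    msg <- c(msg, paste("snpMap must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@snpMap$snp_id))
      msg <- c(msg, "snp_id values must be unique")
    if (any(object@snpMap$pos_bp < 1, na.rm = TRUE))
      msg <- c(msg, "pos_bp must be >= 1")
  }
  if (!"sample_id" %in% names(object@samples))
    msg <- c(msg, "samples must have a sample_id column")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosages individuals x SNPs dosage matrix (0/1/2/NA).
#' @param snpMap data.frame with columns snp_id, chrom, pos_bp, allele_ref,
#'   allele_alt.
#' @param samples data.frame with a sample_id column (breed, sex, ... optional).
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosages, snpMap, samples) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (ncol(dosages) != nrow(snpMap))
    stop("ncol(dosages) must equal nrow(snpMap)")
  if (nrow(dosages) != nrow(samples))
    stop("nrow(dosages) must equal nrow(samples)")
  rownames(dosages) <- as.character(samples$sample_id)
  colnames(dosages) <- as.character(snpMap$snp_id)
  new("GenotypeData", dosages = dosages,
      snpMap = as.data.frame(snpMap), samples = as.data.frame(samples))
}

#' @describeIn GenotypeData dosage matrix accessor
#' @param x,object a GenotypeData
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname GenotypeData
#' @export
setMethod("dosages", "GenotypeData", function(x) x@dosages)

#' @rdname GenotypeData
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @rdname GenotypeData
#' @export
setMethod("snpMap", "GenotypeData", function(x) x@snpMap)

#' @rdname GenotypeData
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @rdname GenotypeData
#' @export
setMethod("sampleInfo", "GenotypeData", function(x) x@samples)

#' @rdname GenotypeData
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))
#' @rdname GenotypeData
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@dosages))

#' @rdname GenotypeData
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname GenotypeData
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosages))

#' @rdname GenotypeData
#' @param i sample index (logical, integer or sample_id character)
#' @param j SNP index (logical, integer or snp_id character)
#' @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosages))
  if (missing(j)) j <- seq_len(ncol(x@dosages))
  if (is.character(i)) i <- match(i, x@samples$sample_id)
  if (is.character(j)) j <- match(j, x@snpMap$snp_id)
  GenotypeData(x@dosages[i, j, drop = FALSE],
               x@snpMap[j, , drop = FALSE],
               x@samples[i, , drop = FALSE])
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosages), "individuals x",
      ncol(object@dosages), "SNPs\n")
  cat("  chromosomes:", length(unique(object@snpMap$chrom)), "\n")
  miss <- mean(is.na(object@dosages))
  cat(sprintf("  missing rate: %.4f\n", miss))
  if ("breed" %in% names(object@samples)) {
    tb <- table(object@samples$breed)
    cat("  breeds:", paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
})

#' GRM: VanRaden genomic relationship matrix
#'
#' Symmetric genomic relationship matrix G = ZZ'/(2*sum p_i (1-p_i)) where Z
#' is the 2p-centred dosage matrix. Carries its denominator and the SNP count
#' it was built from.
#'
#' @slot matrix symmetric n x n numeric matrix.
#' @slot sampleIds character vector of individual identifiers.
#' @slot nSnpsUsed number of SNPs entering the matrix.
#' @slot denominator the VanRaden scaling 2*sum p_i(1-p_i).
#' @slot freqSource "in-sample" or "supplied".
#' @export
setClass("GRM",
  representation(
    matrix      = "matrix",
    sampleIds   = "character",
    nSnpsUsed   = "integer",
    denominator = "numeric",
    freqSource  = "character"
  )
)

setValidity("GRM", function(object) {
  msg <- character()
  m <- object@matrix
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (nrow(m) != length(object@sampleIds))
    msg <- c(msg, "sampleIds length must match matrix dimension")
  if (max(abs(m - t(m))) > 1e-10)
    msg <- c(msg, "matrix must be symmetric to 1e-10")
  if (object@denominator <= 0) msg <- c(msg, "denominator must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname GRM-class
#' @param x a GRM
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))
#' @rdname GRM-class
#' @export
setMethod("grmMatrix", "GRM", function(x) x@matrix)

#' @rdname GRM-class
#' @export
setGeneric("grmDenominator", function(x) standardGeneric("grmDenominator"))
#' @rdname GRM-class
#' @export
setMethod("grmDenominator", "GRM", function(x) x@denominator)

#' @rdname GRM-class
#' @export
setMethod("nSamples", "GRM", function(x) nrow(x@matrix))

setMethod("show", "GRM", function(object) {
  cat("GRM:", nrow(object@matrix), "individuals,",
      object@nSnpsUsed, "SNPs, denominator",
      format(object@denominator, digits = 6),
      sprintf("(freqs %s)\n", object@freqSource))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f\n",
              mean(diag(object@matrix)),
              mean(object@matrix[upper.tri(object@matrix)])))
})
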