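#' Harmonize effect alleles across GWAS summary tables
#'
#' Chooses the reference effect allele per SNP from the first study carrying
#' it; studies reporting the swapped allele pair have their betas
#' sign-flipped, and records whose allele pair neither matches nor swaps are
#' dropped (count in `attr(, "n_dropped")`). No strand flipping is
#' attempted: an A/G vs T/C record is incompatible here.
#'
#' @param studies list of data.frames with columns snp_id, effect_allele,
#'   other_allele, beta, se, p_value (and optionally study_id).
#' @return list of aligned data.frames in the input order.
#' @export
harmonizeAlleles <- function(studies) {
  stopifnot(length(studies) >= 1)
  ref <- new.env(parent = emptyenv())
  for (s in studies) {
    for (i in seq_len(nrow(s))) {
      id <- s$snp_id[i]
      if (is.null(ref[[id]]))
        ref[[id]] <- c(s$effect_allele[i], s$other_allele[i])
    }
  }
  nDropped <- 0L
  out <- lapply(studies, function(s) {
    keep <- rep(TRUE, nrow(s))
    for (i in seq_len(nrow(s))) {
      r <- ref[[s$snp_id[i]]]
      ea <- s$effect_allele[i]; oa <- s$other_allele[i]
      if (ea == r[1] && oa == r[2]) next
      if (ea == r[2] && oa == r[1]) {
        s$beta[i] <- -s$beta[i]
        s$effect_allele[i] <- r[1]
        s$other_allele[i] <- r[2]
      } else {
        keep[i] <- FALSE
        nDropped <<- nDropped + 1L
      }
    }
    s[keep, , drop = FALSE]
  })
  attr(out, "n_dropped") <- nDropped
  out
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Per SNP: weights w_i = 1/se_i^2, pooled beta = sum(w b)/sum(w), pooled
#' se = 1/sqrt(sum w), z = beta/se, two-sided normal p. SNPs present in a
#' single study pass through with that study's values by default (union
#' behaviour); `commonOnly = TRUE` restricts to SNPs present in every
#' study.
#'
#' @param studies list of *harmonized* summary data.frames (see
#'   [harmonizeAlleles()]).
#' @param commonOnly keep only SNPs shared by all studies.
#' @return data.frame: snp_id, effect_allele, other_allele, n_studies,
#'   beta, se, z, p_value, direction.
#' @export
inverseVarianceMeta <- function(studies, commonOnly = FALSE) {
  stopifnot(length(studies) >= 1)
  tab <- do.call(rbind, lapply(seq_along(studies), function(i) {
    s <- studies[[i]]
    stopifnot(all(s$se > 0))
    data.frame(study = i, snp_id = s$snp_id,
               effect_allele = s$effect_allele, other_allele = s$other_allele,
               beta = s$beta, se = s$se, stringsAsFactors = FALSE)
  }))
  sp <- split(tab, tab$snp_id)
  if (commonOnly) sp <- sp[vapply(sp, nrow, 0L) == length(studies)]
  rows <- lapply(sp, function(g) {
    g <- g[order(g$study), , drop = FALSE]
    w <- 1 / g$se^2
    beta <- sum(w * g$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    z <- beta / se
    data.frame(
      snp_id = g$snp_id[1],
      effect_allele = g$effect_allele[1], other_allele = g$other_allele[1],
      n_studies = nrow(g), beta = beta, se = se, z = z,
      p_value = 2 * pnorm(-abs(z)),
      direction = paste(ifelse(g$beta >= 0, "+", "-"), collapse = ""),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$snp_id), , drop = FALSE]
}

#' Thresholds and hit extraction for meta-analysis results
#'
#' The Bonferroni thresholds of the chip analysis are reused (same number
#' of tests M), then hits are partitioned exactly as for the single-breed
#' scan.
#'
#' @param records an [inverseVarianceMeta()] table.
#' @param mTests number of tests of the chip analysis.
#' @param alpha family-wise error rate.
#' @return list: `thresholds` and the `significant`/`suggestive` partitions.
#' @export
metaHits <- function(records, mTests, alpha = 0.05) {
  th <- bonferroniThresholds(mTests, alpha)
  if (nrow(records) == 0)
    return(list(thresholds = th,
                significant = records, suggestive = records))
  c(list(thresholds = th), extractHits(records, th))
}
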