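#' Pool significant variants from all GWAS methods into a selection panel
#'
#' Union of (i) chip mixed-model hits, (ii) dense-panel mixed-model hits,
#' (iii) meta-analysis hits and (iv) all chip SNPs falling inside
#' significant BayesC windows, with per-SNP provenance tags (CL, IL, META,
#' CB). Dense-panel hits absent from the chip are retained in the set and
#' flagged via `on_panel = FALSE`; they are used only when the prediction
#' genotypes include them.
#'
#' @param clHits,ilHits,metaHitsDf data.frames with at least `snp_id`
#'   (and ideally `chrom`, `position`), or `NULL`.
#' @param cbWindows significant-window table ([significantWindows()]) or
#'   `NULL`. Window intervals are half-open \[start_bp, end_bp).
#' @param snpMap chip SNP map (data.frame with snp_id, chrom, pos_bp) used
#'   for window-to-SNP expansion and panel membership.
#' @return data.frame of class `SelectionSet`: snp_id, chrom, pos_bp, tags
#'   (comma-separated provenance), on_panel.
#' @export
buildSigPanel <- function(clHits = NULL, ilHits = NULL, metaHitsDf = NULL,
                          cbWindows = NULL, snpMap) {
  stopifnot(all(c("snp_id", "chrom", "pos_bp") %in% names(snpMap)))
  entries <- list()
  addHits <- function(df, tag) {
    if (is.null(df) || nrow(df) == 0) return()
    pos <- if ("position" %in% names(df)) df$position else
      if ("pos_bp" %in% names(df)) df$pos_bp else
      snpMap$pos_bp[match(df$snp_id, snpMap$snp_id)]
    chr <- if ("chrom" %in% names(df)) df$chrom else
      snpMap$chrom[match(df$snp_id, snpMap$snp_id)]
    entries[[length(entries) + 1]] <<- data.frame(
      snp_id = df$snp_id, chrom = chr, pos_bp = pos, tag = tag,
      stringsAsFactors = FALSE)
  }
  addHits(clHits, "CL")
  addHits(ilHits, "IL")
  addHits(metaHitsDf, "META")
  if (!is.null(cbWindows) && nrow(cbWindows) > 0) {
    for (i in seq_len(nrow(cbWindows))) {
      inWin <- snpMap$chrom == cbWindows$chrom[i] &
        snpMap$pos_bp >= cbWindows$start_bp[i] &
        snpMap$pos_bp < cbWindows$end_bp[i]
      if (any(inWin))
        entries[[length(entries) + 1]] <- data.frame(
          snp_id = snpMap$snp_id[inWin], chrom = snpMap$chrom[inWin],
          pos_bp = snpMap$pos_bp[inWin], tag = "CB",
          stringsAsFactors = FALSE)
    }
  }
  if (!length(entries))
    stop("no significant variants to pool; fall back to single-kernel GBLUP")
  all <- do.call(rbind, entries)
  sp <- split(all, all$snp_id)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(snp_id = g$snp_id[1], chrom = g$chrom[1], pos_bp = g$pos_bp[1],
               tags = paste(sort(unique(g$tag)), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out$on_panel <- out$snp_id %in% snpMap$snp_id
  out <- out[order(out$chrom, out$pos_bp, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("SelectionSet", "data.frame")
  out
}

#' Assign the containing or nearest gene to each hit
#'
#' A hit inside a gene interval gets that gene with distance 0; otherwise
#' the nearest gene within `flank` bp is reported with its distance, else
#' no assignment. Gene intervals may be a data.frame (chrom, start, end,
#' name), a `GRanges`, or a path to a GFF3/BED file (imported with
#' rtracklayer).
#'
#' @param hits data.frame with snp_id, chrom and position (or pos_bp).
#' @param geneIntervals see above.
#' @param flank maximum distance in bp (default 500000).
#' @return `hits` with columns `gene` and `gene_distance` appended.
#' @export
annotateNearestGene <- function(hits, geneIntervals, flank = 5e5) {
  pos <- if ("position" %in% names(hits)) hits$position else hits$pos_bp
  stopifnot(!is.null(pos), "chrom" %in% names(hits))
  if (is.character(geneIntervals)) {
    gr <- tryCatch(suppressWarnings(rtracklayer::import(geneIntervals)),
                   error = function(e) stop("failed to parse interval file '",
                                            geneIntervals, "': ",
                                            conditionMessage(e)))
    nm <- if (!is.null(gr$Name)) gr$Name else if (!is.null(gr$name)) gr$name
      else if (!is.null(gr$ID)) gr$ID else as.character(seq_along(gr))
    names(gr) <- nm
  } else if (is(geneIntervals, "GRanges")) {
    gr <- geneIntervals
    if (is.null(names(gr)))
      names(gr) <- if (!is.null(gr$name)) gr$name else as.character(seq_along(gr))
  } else {
    df <- as.data.frame(geneIntervals)
    stopifnot(all(c("chrom", "start", "end", "name") %in% names(df)))
    gr <- GenomicRanges::GRanges(
      seqnames = as.character(df$chrom),
      ranges = IRanges::IRanges(start = df$start, end = df$end))
    names(gr) <- df$name
  }
  q <- GenomicRanges::GRanges(seqnames = as.character(hits$chrom),
                              ranges = IRanges::IRanges(start = pos, width = 1))
  hitGene <- rep(NA_character_, nrow(hits))
  hitDist <- rep(NA_real_, nrow(hits))
  # containing gene first (distance 0); first overlap wins on ties
  ov <- GenomicRanges::findOverlaps(q, gr, select = "first")
  inGene <- !is.na(ov)
  hitGene[inGene] <- names(gr)[ov[inGene]]
  hitDist[inGene] <- 0
  # otherwise nearest gene within the flank; the reported distance is the
  # base-pair offset to the gene boundary (GenomicRanges counts the strictly
  # intervening positions, hence the +1)
  if (any(!inGene)) {
    nn <- GenomicRanges::distanceToNearest(q[!inGene], gr)
    qi <- which(!inGene)[S4Vectors::queryHits(nn)]
    si <- S4Vectors::subjectHits(nn)
    dd <- S4Vectors::mcols(nn)$distance + 1
    ok <- dd <= flank
    hitGene[qi[ok]] <- names(gr)[si[ok]]
    hitDist[qi[ok]] <- dd[ok]
  }
  hits$gene <- hitGene
  hits$gene_distance <- hitDist
  hits
}
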