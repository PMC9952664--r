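# Readers and writers: PLINK bed/bim/fam (SNP-major binary), VCF with GT
# calls, and tab-separated phenotype/covariate tables.

#' Write genotypes as a PLINK bed/bim/fam fileset
#'
#' SNP-major bed with the standard magic bytes (0x6c 0x1b 0x01). A1 is the
#' alternate (counted) allele and A2 the reference, so dosage 2 encodes
#' homozygous A1.
#'
#' @param genotypes a [GenotypeData-class].
#' @param prefix output path prefix (writes prefix.bed/.bim/.fam).
#' @return `prefix`, invisibly.
#' @export
writePlink <- function(genotypes, prefix) {
  stopifnot(is(genotypes, "GenotypeData"))
  map <- snpMap(genotypes)
  smp <- sampleInfo(genotypes)
  d <- dosages(genotypes)
  n <- nrow(d); M <- ncol(d)

  bim <- data.frame(map$chrom, map$snp_id, 0, map$pos_bp,
                    map$allele_alt, map$allele_ref)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(
    if ("breed" %in% names(smp)) smp$breed else 0,
    smp$sample_id, 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  # 2-bit codes, low bits first: 00 hom A1 (dosage 2), 10 het, 11 hom A2, 01 missing
  code <- matrix(3L, n, M)                       # hom A2 = dosage 0
  code[!is.na(d) & d == 2] <- 0L
  code[!is.na(d) & d == 1] <- 2L
  code[is.na(d)] <- 1L
  nBytes <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- 4 * nBytes - n
  for (j in seq_len(M)) {
    cj <- c(code[, j], integer(pad))
    m4 <- matrix(cj, nrow = 4)
    bytes <- m4[1, ] + m4[2, ] * 4L + m4[3, ] * 16L + m4[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a PLINK bed/bim/fam fileset
#'
#' @param prefix path prefix of the fileset.
#' @return a [GenotypeData-class]; fam family IDs become the `breed`
#'   column when non-trivial.
#' @export
readPlink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos_bp",
                                  "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); M <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed file: bad magic bytes")
  nBytes <- ceiling(n / 4)
  raw <- readBin(con, "raw", nBytes * M)
  if (length(raw) < nBytes * M) stop("truncated bed file")
  v <- as.integer(raw)
  codes <- cbind(v %% 4L, (v %/% 4L) %% 4L, (v %/% 16L) %% 4L, (v %/% 64L) %% 4L)
  lookup <- c(2, NA, 1, 0)                       # 00, 01, 10, 11
  d <- matrix(NA_real_, n, M)
  for (j in seq_len(M)) {
    cj <- t(codes[(j - 1) * nBytes + seq_len(nBytes), , drop = FALSE])
    d[, j] <- lookup[cj[seq_len(n)] + 1L]
  }
  map <- data.frame(snp_id = bim$snp_id, chrom = bim$chrom,
                    pos_bp = bim$pos_bp, allele_ref = bim$a2,
                    allele_alt = bim$a1, stringsAsFactors = FALSE)
  smp <- data.frame(sample_id = as.character(fam$V2), stringsAsFactors = FALSE)
  if (length(unique(fam$V1)) > 1 || !all(fam$V1 %in% c(0, "0")))
    smp$breed <- as.character(fam$V1)
  GenotypeData(d, map, smp)
}

#' Write genotypes as an uncompressed VCF
#'
#' Minimal VCFv4.2 with GT calls; REF/ALT come from the SNP map and dosages
#' count the ALT allele.
#'
#' @param genotypes a [GenotypeData-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeVcfGenotypes <- function(genotypes, path) {
  stopifnot(is(genotypes, "GenotypeData"))
  map <- snpMap(genotypes)
  smp <- sampleInfo(genotypes)
  d <- dosages(genotypes)
  gtOf <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=growsel",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", as.character(smp$sample_id)), collapse = "\t"))
  body <- vapply(seq_len(ncol(d)), function(j) {
    gt <- ifelse(is.na(d[, j]), "./.", gtOf[d[, j] + 1])
    paste(c(map$chrom[j], map$pos_bp[j], map$snp_id[j], map$allele_ref[j],
            map$allele_alt[j], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read genotypes from a VCF (GT field)
#'
#' Parses with vcfR; ALT-allele dosage is the count of non-reference
#' alleles in the GT call, `NA` for missing.
#'
#' @param path VCF file path (plain or gzipped).
#' @return a [GenotypeData-class].
#' @export
readVcfGenotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleleCount <- function(x) {
    if (is.na(x) || x %in% c("./.", ".|.", ".")) return(NA_real_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  }
  d <- t(apply(gt, 1, function(r) vapply(r, alleleCount, numeric(1))))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  map <- data.frame(snp_id = ids, chrom = fix$CHROM,
                    pos_bp = as.integer(fix$POS),
                    allele_ref = fix$REF, allele_alt = fix$ALT,
                    stringsAsFactors = FALSE)
  smp <- data.frame(sample_id = colnames(gt), stringsAsFactors = FALSE)
  GenotypeData(t(d), map, smp)
}

#' Read / write tab-separated phenotype tables
#'
#' Plain TSV with a header row; `NA` encodes missing.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readPhenoTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname readPhenoTable
#' @param x data.frame to write.
#' @export
writePhenoTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
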