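# Minimal PLINK 1 binary (bed/bim/fam) reader and writer, SNP-major layout.
# Genotypes are stored as counts of the bim A1 allele (the counted / alt
# allele): 2-bit codes 00 = 2 copies of A1, 10 = 1 copy, 11 = 0 copies,
# 01 = missing.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK bed/bim/fam fileset into a reference panel
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [reference_panel()] whose genotypes count the bim A1 (alt)
#'   allele.
#' @export
read_plink <- function(prefix) {
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(fam); p <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), what = "raw",
                 n = 3 + p * ceiling(n / 4))
  if (length(raw) < 3 || !identical(raw[1:3], BED_MAGIC))
    stop(prefix, ".bed is not a SNP-major PLINK v1 bed file")
  body <- raw[-(1:3)]
  bps <- ceiling(n / 4)
  if (length(body) != p * bps) stop("bed payload size mismatch")
  # decode 2-bit codes: per byte, samples fill from the low bits
  m <- matrix(as.integer(body), nrow = bps, ncol = p)
  geno <- matrix(NA_real_, n, p)
  lut <- c(2, NA, 1, 0) # codes 0b00, 0b01, 0b10, 0b11
  for (shift in 0:3) {
    samp <- seq.int(shift + 1L, by = 4L, length.out = bps)
    samp_ok <- samp <= n
    code <- (m[samp_ok, , drop = FALSE] %/% 4L^shift) %% 4L
    geno[samp[samp_ok], ] <- lut[code + 1L]
  }
  snps <- data.frame(snp_id = as.character(bim$snp_id),
                     chrom = as.character(bim$chrom), pos = bim$pos,
                     ref = as.character(bim$a2), alt = as.character(bim$a1),
                     cm = bim$cm, stringsAsFactors = FALSE)
  reference_panel(as.character(fam[[2]]), geno, snps)
}

#' Write a reference panel as a PLINK bed/bim/fam fileset
#'
#' @param panel A [reference_panel()]; genotypes must be hard calls in
#'   `{0, 1, 2, NA}`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  g <- panel$genotypes
  if (!all(g %in% c(0, 1, 2) | is.na(g)))
    stop("write_plink requires hard-call genotypes in {0, 1, 2, NA}")
  n <- nrow(g); p <- ncol(g)
  s <- panel$snps
  cm <- if ("cm" %in% names(s)) ifelse(is.na(s$cm), 0, s$cm) else 0
  write.table(data.frame(s$chrom, s$snp_id, cm, s$pos, s$alt, s$ref),
              paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(panel$sample_ids, panel$sample_ids, 0, 0, 0, -9),
              paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  # encode: genotype -> 2-bit code (count of A1)
  code <- matrix(1L, n, p) # default = missing (0b01)
  code[!is.na(g) & g == 2] <- 0L
  code[!is.na(g) & g == 1] <- 2L
  code[!is.na(g) & g == 0] <- 3L
  bps <- ceiling(n / 4)
  pad <- bps * 4 - n
  if (pad > 0) code <- rbind(code, matrix(0L, pad, p))
  idx <- seq.int(1L, by = 4L, length.out = bps)
  packed <- code[idx, , drop = FALSE] +
    4L * code[idx + 1L, , drop = FALSE] +
    16L * code[idx + 2L, , drop = FALSE] +
    64L * code[idx + 3L, , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  writeBin(as.raw(packed), con)
  invisible(prefix)
}

#' Read a VCF into a reference panel
#'
#' Biallelic sites only; genotypes become counts of the ALT allele.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @return A [reference_panel()].
#' @export
read_vcf_panel <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF panels requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- !grepl(",", fix[, "ALT"], fixed = TRUE)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  counts <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_real_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  })
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  snps <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                     pos = as.numeric(fix[, "POS"]), ref = fix[, "REF"],
                     alt = fix[, "ALT"], stringsAsFactors = FALSE)
  reference_panel(colnames(gt), t(counts), snps)
}
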