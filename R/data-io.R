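# Readers, filters and harmonization for summary-level eQTL/GWAS data,
# reference genotype panels, genetic maps and gene annotations. All tables
# meet at a shared per-gene SNP data model: a data frame with columns
# snp_id, chrom, pos, ref, alt and optionally maf (folded, <= 0.5) and cm.

STRAND_AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

validate_snp_info <- function(snps) {
  stopifnot(is.data.frame(snps))
  required <- c("snp_id", "chrom", "pos", "ref", "alt")
  missing <- setdiff(required, names(snps))
  if (length(missing))
    stop("SNP table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(snps) == 0) return(invisible(snps))
  if (any(snps$pos <= 0)) stop("SNP positions must be positive (1-based)")
  if (any(!nzchar(snps$ref)) || any(!nzchar(snps$alt)))
    stop("alleles must be non-empty")
  if (any(snps$ref == snps$alt)) stop("ref and alt alleles must differ")
  if ("maf" %in% names(snps)) {
    m <- snps$maf[!is.na(snps$maf)]
    if (any(m < 0 | m > 0.5)) stop("maf must lie in [0, 0.5]")
  }
  invisible(snps)
}

#' Per-gene eQTL summary-statistics table
#'
#' Container for the cis-eQTL summary records of one gene: SNP metadata,
#' eQTL z-scores and the per-SNP sample sizes. Per-SNP sample sizes are kept
#' as given (meta-analyses report a different N for each SNP; the largest
#' cohort size is never substituted).
#'
#' @param gene_id Gene identifier.
#' @param snps Data frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt` and optionally `maf`, `cm`.
#' @param z Numeric vector of eQTL z-scores, one per SNP.
#' @param n Integer vector of per-SNP sample sizes, all `>= 2`.
#' @return An object of class `eqtl_summary`.
#' @export
eqtl_summary <- function(gene_id, snps, z, n) {
  validate_snp_info(snps)
  if (length(z) != nrow(snps) || length(n) != nrow(snps))
    stop("z, n and SNP table must have equal length")
  if (anyDuplicated(snps$snp_id))
    stop("duplicate SNP id(s) within gene ", gene_id, ": ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  if (length(n) && any(!is.finite(n) | n < 2))
    stop("per-SNP sample sizes must be finite and >= 2")
  structure(list(gene_id = gene_id, snps = snps,
                 z = as.numeric(z), n = as.numeric(n)),
            class = "eqtl_summary")
}

#' GWAS summary-statistics table
#'
#' @param snps SNP metadata data frame (see [eqtl_summary()]).
#' @param z Numeric vector of GWAS z-scores, sign-aligned to the counted
#'   (alt) allele.
#' @return An object of class `gwas_summary`.
#' @export
gwas_summary <- function(snps, z) {
  validate_snp_info(snps)
  if (length(z) != nrow(snps)) stop("z and SNP table must have equal length")
  if (length(z) && any(!is.finite(z))) stop("GWAS z-scores must be finite")
  structure(list(snps = snps, z = as.numeric(z)), class = "gwas_summary")
}

#' Gene annotation record
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome.
#' @param tss,tes Transcription start/end site (1-based bp, `tss <= tes`).
#' @return An object of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, chrom, tss, tes) {
  tss <- as.numeric(tss); tes <- as.numeric(tes)
  if (tss <= 0 || tes <= 0) stop("tss and tes must be positive")
  if (tss > tes) stop("tss must be <= tes")
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 tss = tss, tes = tes), class = "gene_annotation")
}

#' Reference genotype panel
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param genotypes Numeric samples x SNPs matrix of allele counts in
#'   `{0, 1, 2}` (or dosages in `[0, 2]`); `NA` marks missing calls.
#'   Counts are of the `alt` allele.
#' @param snps SNP metadata data frame aligned with the columns.
#' @return An object of class `reference_panel`.
#' @export
reference_panel <- function(sample_ids, genotypes, snps) {
  validate_snp_info(snps)
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(snps))
    stop("genotype columns must match the SNP table")
  if (nrow(genotypes) != length(sample_ids))
    stop("genotype rows must match sample_ids")
  if (ncol(genotypes) && any(colSums(!is.na(genotypes)) == 0))
    stop("at least one SNP has 100% missing genotypes")
  colnames(genotypes) <- snps$snp_id
  structure(list(sample_ids = as.character(sample_ids),
                 genotypes = genotypes, snps = snps),
            class = "reference_panel")
}

#' @export
print.eqtl_summary <- function(x, ...) {
  cat("eQTL summary for", x$gene_id, "-", nrow(x$snps), "SNPs\n")
  invisible(x)
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("Reference panel:", length(x$sample_ids), "samples x",
      nrow(x$snps), "SNPs\n")
  invisible(x)
}

#' Column-name mappings for summary-statistics text dialects
#'
#' Defaults follow the eQTLGen cis-eQTL release column names; GWAS defaults
#' follow the common `SNP/CHR/POS/A1/A2/Z` convention with `A1` the counted
#' allele. Override any element to adapt to another dialect.
#'
#' @param ... Named overrides of individual column names.
#' @return Named character vector mapping roles to file column names.
#' @export
eqtl_columns <- function(...) {
  cols <- c(snp_id = "SNP", gene_id = "Gene", chrom = "SNPChr",
            pos = "SNPPos", alt = "AssessedAllele", ref = "OtherAllele",
            z = "Zscore", n = "NrSamples")
  override_columns(cols, list(...))
}

#' @rdname eqtl_columns
#' @export
gwas_columns <- function(...) {
  cols <- c(snp_id = "SNP", chrom = "CHR", pos = "POS",
            alt = "A1", ref = "A2", z = "Z")
  override_columns(cols, list(...))
}

override_columns <- function(cols, overrides) {
  if (!length(overrides)) return(cols)
  bad <- setdiff(names(overrides), names(cols))
  if (length(bad)) stop("unknown column role(s): ", paste(bad, collapse = ", "))
  cols[names(overrides)] <- unlist(overrides)
  cols
}

read_summary_file <- function(path, columns) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(columns), names(df))
  if (length(missing))
    stop("file ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Load per-gene cis-eQTL summary statistics from a tab-delimited file
#'
#' Reads an eQTLGen-style tab-delimited file and returns the rows for one
#' gene, in file order. An empty result (gene absent from the file) is a
#' valid zero-row table, not an error.
#'
#' @param path Path to the tab-delimited file (header required).
#' @param gene A [gene_annotation()] whose `gene_id` selects the rows.
#' @param columns Column-name mapping, see [eqtl_columns()].
#' @return An [eqtl_summary()] for the gene.
#' @export
load_eqtl_summary <- function(path, gene, columns = eqtl_columns()) {
  df <- read_summary_file(path, columns)
  df <- df[df[[columns[["gene_id"]]]] == gene$gene_id, , drop = FALSE]
  snps <- data.frame(snp_id = as.character(df[[columns[["snp_id"]]]]),
                     chrom = as.character(df[[columns[["chrom"]]]]),
                     pos = as.numeric(df[[columns[["pos"]]]]),
                     ref = as.character(df[[columns[["ref"]]]]),
                     alt = as.character(df[[columns[["alt"]]]]),
                     stringsAsFactors = FALSE)
  eqtl_summary(gene$gene_id, snps, as.numeric(df[[columns[["z"]]]]),
               as.numeric(df[[columns[["n"]]]]))
}

#' Load GWAS summary statistics from a tab-delimited file
#'
#' @inheritParams load_eqtl_summary
#' @param columns Column-name mapping, see [gwas_columns()].
#' @return A [gwas_summary()].
#' @export
load_gwas_summary <- function(path, columns = gwas_columns()) {
  df <- read_summary_file(path, columns)
  snps <- data.frame(snp_id = as.character(df[[columns[["snp_id"]]]]),
                     chrom = as.character(df[[columns[["chrom"]]]]),
                     pos = as.numeric(df[[columns[["pos"]]]]),
                     ref = as.character(df[[columns[["ref"]]]]),
                     alt = as.character(df[[columns[["alt"]]]]),
                     stringsAsFactors = FALSE)
  gwas_summary(snps, as.numeric(df[[columns[["z"]]]]))
}

#' Write summary tables back to tab-delimited text
#'
#' Inverse of [load_eqtl_summary()] / [load_gwas_summary()]: a table written
#' here and re-read is equal field for field.
#'
#' @param table An `eqtl_summary` or `gwas_summary`.
#' @param path Output path.
#' @param columns Column-name mapping used for the header.
#' @return The path, invisibly.
#' @export
write_summary <- function(table, path,
                          columns = if (inherits(table, "eqtl_summary"))
                            eqtl_columns() else gwas_columns()) {
  s <- table$snps
  df <- data.frame(s$snp_id, s$chrom, s$pos, s$alt, s$ref, table$z,
                   stringsAsFactors = FALSE)
  names(df) <- columns[c("snp_id", "chrom", "pos", "alt", "ref", "z")]
  if (inherits(table, "eqtl_summary")) {
    df[[columns[["gene_id"]]]] <- table$gene_id
    df[[columns[["n"]]]] <- table$n
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene annotations (4-column TSV or GTF)
#'
#' The primary format is a header-bearing tab-delimited file with columns
#' `gene_id`, `chrom`, `tss`, `tes`. Files ending in `.gtf`/`.gff` are
#' parsed minimally: `gene` features only, with `tss = start`, `tes = end`.
#'
#' @param path Annotation file path.
#' @return A list of [gene_annotation()] objects, named by gene id.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.(gtf|gff3?)$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    f <- f[vapply(f, function(x) length(x) >= 9 && x[3] == "gene", logical(1))]
    if (!length(f)) stop("no 'gene' features found in ", path)
    out <- lapply(f, function(x) {
      id <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", x[9])
      gene_annotation(id, x[1], as.numeric(x[4]), as.numeric(x[5]))
    })
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "tes")
    if (!all(need %in% names(df)))
      stop("annotation file needs columns: ", paste(need, collapse = ", "))
    out <- lapply(seq_len(nrow(df)), function(i)
      gene_annotation(df$gene_id[i], df$chrom[i], df$tss[i], df$tes[i]))
  }
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out
}

#' Read a genetic map (bp to centimorgan)
#'
#' Accepts the 1000 Genomes OMNI per-chromosome layout (three columns:
#' position in bp, recombination rate, cumulative map in cM) or any
#' tab/space-delimited file whose first and last columns are bp and cM.
#'
#' @param path Map file path.
#' @return Data frame with columns `pos` (bp) and `cm`, sorted by position.
#' @export
read_genetic_map <- function(path) {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("genetic map needs at least position and cM columns")
  map <- data.frame(pos = as.numeric(df[[1]]),
                    cm = as.numeric(df[[ncol(df)]]))
  if (nrow(map) == 0) stop("empty genetic map: ", path)
  map[order(map$pos), , drop = FALSE]
}

#' Restrict a table to a gene's cis window
#'
#' Keeps SNPs with `tss - window_bp <= pos <= tes + window_bp` (closed
#' interval, 1-based, so boundary SNPs are retained).
#'
#' @param x An `eqtl_summary`, `gwas_summary` or `reference_panel`.
#' @param gene A [gene_annotation()].
#' @param window_bp Window half-width in bp (default 1 Mb).
#' @return Object of the same class, subset to the window.
#' @export
restrict_to_cis_window <- function(x, gene, window_bp = 1e6) {
  stopifnot(window_bp > 0)
  snps <- if (inherits(x, "reference_panel") || inherits(x, "gwas_summary"))
    x$snps else x$snps
  keep <- snps$chrom == gene$chrom &
    snps$pos >= gene$tss - window_bp & snps$pos <= gene$tes + window_bp
  subset_snp_table(x, which(keep))
}

# Index-subset any of the SNP-carrying containers, preserving class.
subset_snp_table <- function(x, idx) {
  if (inherits(x, "eqtl_summary")) {
    eqtl_summary(x$gene_id, x$snps[idx, , drop = FALSE], x$z[idx], x$n[idx])
  } else if (inherits(x, "gwas_summary")) {
    gwas_summary(x$snps[idx, , drop = FALSE], x$z[idx])
  } else if (inherits(x, "reference_panel")) {
    reference_panel(x$sample_ids, x$genotypes[, idx, drop = FALSE],
                    x$snps[idx, , drop = FALSE])
  } else stop("unsupported table type")
}

#' Per-SNP minor allele frequency of a reference panel
#'
#' @param panel A [reference_panel()].
#' @return Numeric vector of folded allele frequencies (all `<= 0.5`).
#' @export
panel_maf <- function(panel) {
  af <- colMeans(panel$genotypes, na.rm = TRUE) / 2
  pmin(af, 1 - af)
}

is_strand_ambiguous <- function(ref, alt) {
  paste(ref, alt, sep = "/") %in% STRAND_AMBIGUOUS
}

is_biallelic_snv <- function(ref, alt) {
  base <- c("A", "C", "G", "T")
  ref %in% base & alt %in% base
}

#' SNP quality filters for model training
#'
#' Removes SNPs that are rare in the reference panel (`MAF < maf_min`;
#' the boundary value is kept), not biallelic single-nucleotide variants,
#' strand-ambiguous (A/T or C/G pairs), or absent from a SNP whitelist
#' (e.g. HapMap3) when one is supplied. Order is preserved; applying the
#' filter twice equals applying it once.
#'
#' @param table An `eqtl_summary` (or `gwas_summary`).
#' @param panel [reference_panel()] supplying allele frequencies; SNPs
#'   missing from the panel are dropped.
#' @param hapmap3_ids Character vector of allowed SNP ids; `character(0)`
#'   (default) skips the whitelist filter.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @return The surviving subset, same class as `table`.
#' @export
filter_snps <- function(table, panel, hapmap3_ids = character(),
                        maf_min = 0.01) {
  s <- table$snps
  maf <- panel_maf(panel)[match(s$snp_id, panel$snps$snp_id)]
  keep <- !is.na(maf) & maf >= maf_min &
    is_biallelic_snv(s$ref, s$alt) & !is_strand_ambiguous(s$ref, s$alt)
  if (length(hapmap3_ids)) keep <- keep & s$snp_id %in% hapmap3_ids
  subset_snp_table(table, which(keep))
}

#' Harmonize summary-statistic alleles to a reference panel
#'
#' Restricts to SNPs present in both the summary table and the panel,
#' aligns z-score signs to the panel's counted (alt) allele, and orders the
#' output to match the panel. Where the summary's (ref, alt) pair equals the
#' panel's, z is kept; where the pair is swapped, z is sign-flipped; any
#' other pair (including unresolved strand flips) is dropped. Counts of
#' flipped and dropped SNPs are attached as attributes `n_flipped` and
#' `n_dropped`.
#'
#' @param table An `eqtl_summary` or `gwas_summary`.
#' @param panel A [reference_panel()].
#' @return Harmonized table of the same class, in panel SNP order.
#' @export
harmonize_alleles <- function(table, panel) {
  s <- table$snps
  idx_panel <- which(panel$snps$snp_id %in% s$snp_id)
  idx_tab <- match(panel$snps$snp_id[idx_panel], s$snp_id)
  pr <- panel$snps$ref[idx_panel]; pa <- panel$snps$alt[idx_panel]
  tr <- s$ref[idx_tab]; ta <- s$alt[idx_tab]
  same <- tr == pr & ta == pa
  swap <- tr == pa & ta == pr
  keep <- same | swap
  out <- subset_snp_table(table, idx_tab[keep])
  out$z <- out$z * ifelse(swap[keep], -1, 1)
  # adopt the panel's allele labels so downstream joins are consistent
  out$snps$ref <- pr[keep]; out$snps$alt <- pa[keep]
  attr(out, "n_flipped") <- sum(swap & keep)
  attr(out, "n_dropped") <- nrow(s) - sum(keep)
  out
}

#' Standardize panel genotypes
#'
#' Mean-imputes missing calls per SNP, then centers and scales each column
#' to mean 0, variance 1 (denominator `n`).
#'
#' @param panel A [reference_panel()] or a raw genotype matrix.
#' @return Numeric matrix of standardized genotypes.
#' @export
standardize_genotypes <- function(panel) {
  g <- if (inherits(panel, "reference_panel")) panel$genotypes else panel
  g <- as.matrix(g)
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    na_idx <- which(is.na(g), arr.ind = TRUE)
    g[na_idx] <- mu[na_idx[, 2]]
  }
  ctr <- colMeans(g)
  g <- sweep(g, 2, ctr, "-")
  v <- colMeans(g^2)
  if (any(v == 0)) {
    bad <- colnames(g)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("monomorphic SNP(s): ", paste(bad, collapse = ", "))
  }
  sweep(g, 2, sqrt(v), "/")
}
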