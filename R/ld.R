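# LD estimation: sample correlation from a reference panel plus the
# genetic-distance shrinkage estimator used both in the training objective
# and (by default) in the burden-test variance.

#' LD matrix container
#'
#' @param snp_ids Character vector naming rows/columns.
#' @param values Symmetric correlation matrix with unit diagonal.
#' @param shrunk Logical; has the shrinkage estimator been applied?
#' @param params List of shrinkage parameters (`N_e`, `m`, `c`) or `NULL`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(snp_ids, values, shrunk = FALSE, params = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || nrow(values) != length(snp_ids))
    stop("LD matrix must be square and match snp_ids")
  if (max(abs(values - t(values))) > 1e-12) stop("LD matrix must be symmetric")
  if (any(abs(diag(values) - 1) > 1e-12)) stop("LD matrix must have unit diagonal")
  if (any(values < -1 - 1e-12 | values > 1 + 1e-12))
    stop("LD entries must lie in [-1, 1]")
  dimnames(values) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), values = values,
                 shrunk = shrunk, params = params), class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD matrix: %d SNPs%s\n", length(x$snp_ids),
              if (x$shrunk) " (shrunk)" else ""))
  invisible(x)
}

#' Sample LD correlation matrix from a reference panel
#'
#' Pearson correlations of the (mean-imputed, standardized) genotype
#' columns. Monomorphic SNPs are an error, named.
#'
#' @param panel A [reference_panel()].
#' @return An unshrunk [ld_matrix()].
#' @export
sample_ld <- function(panel) {
  if (length(panel$sample_ids) < 2) stop("need >= 2 samples for LD")
  x <- standardize_genotypes(panel)
  r <- crossprod(x) / nrow(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r[r > 1] <- 1; r[r < -1] <- -1
  ld_matrix(panel$snps$snp_id, r, shrunk = FALSE)
}

#' Genetic-distance shrinkage of an LD matrix
#'
#' Multiplies each off-diagonal entry by `exp(-2 * N_e * c_ij / m)`, where
#' `c_ij` is the genetic distance between SNPs i and j in centimorgans,
#' `N_e` the effective population size and `m` the sample size of the data
#' behind the genetic map. Entries whose factor falls below the threshold
#' `c` are set to exactly zero. With the defaults (N_e = 11,400, m = 183,
#' c = 1e-3) the factor at 0.01 cM is about 0.288 and entries vanish beyond
#' about 0.0554 cM.
#'
#' @param ld An unshrunk [ld_matrix()].
#' @param cm Numeric vector of genetic positions (cM) aligned with the LD
#'   matrix' SNPs; no missing values (interpolate first, see
#'   [interpolate_cm()]).
#' @param N_e Effective population size (default 11,400).
#' @param m Genetic-map sample size (default 183).
#' @param c Zeroing threshold on the shrinkage factor (default 1e-3).
#' @return A shrunk [ld_matrix()].
#' @export
shrink_ld <- function(ld, cm, N_e = 11400, m = 183, c = 1e-3) {
  stopifnot(inherits(ld, "ld_matrix"))
  if (ld$shrunk) stop("LD matrix is already shrunk")
  if (length(cm) != length(ld$snp_ids))
    stop("cm must align with the LD matrix SNPs")
  if (anyNA(cm)) stop("missing cM value(s); interpolate the map first")
  f <- exp(-(2 * N_e / m) * abs(outer(cm, cm, "-")))
  f[f < c] <- 0
  v <- ld$values * f
  diag(v) <- 1
  ld_matrix(ld$snp_ids, v, shrunk = TRUE, params = list(N_e = N_e, m = m, c = c))
}

#' Interpolate genetic positions at SNP sites
#'
#' Linear interpolation of the cumulative map (cM) at each SNP's bp
#' position; positions outside the map range are clamped to the end values.
#'
#' @param snps SNP data frame with a `pos` column (or a vector of bp
#'   positions).
#' @param map Genetic map data frame with `pos` and `cm` columns, sorted by
#'   position (see [read_genetic_map()]).
#' @return Numeric vector of cM positions.
#' @export
interpolate_cm <- function(snps, map) {
  pos <- if (is.data.frame(snps)) snps$pos else as.numeric(snps)
  if (nrow(map) == 0) stop("empty genetic map")
  if (nrow(map) == 1) return(rep(map$cm, length(pos)))
  approx(map$pos, map$cm, xout = pos, rule = 2, ties = "ordered")$y
}

#' Write an LD matrix as gzipped triplet text
#'
#' Debug/interchange format: one line per stored entry
#' (`snp_i snp_j value`), upper triangle including the diagonal.
#'
#' @param ld An [ld_matrix()].
#' @param path Output path (`.gz` applied automatically).
#' @return The path, invisibly.
#' @export
write_ld_triplets <- function(ld, path) {
  ut <- upper.tri(ld$values, diag = TRUE)
  idx <- which(ut, arr.ind = TRUE)
  df <- data.frame(snp_i = ld$snp_ids[idx[, 1]], snp_j = ld$snp_ids[idx[, 2]],
                   r = ld$values[ut])
  con <- gzfile(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
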