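# Synthetic data generation: LD-structured genotypes via a latent-Gaussian
# threshold model with block-AR(1) correlation, expression and phenotype
# generation at specified heritabilities, and derivation of the
# summary-level tables (per-SNP regression z-scores) from individual data.

#' LD model for synthetic genotypes
#'
#' Fixes the gene-level quantities that stay constant across cohorts within
#' a simulation replicate: per-SNP target minor allele frequencies, the
#' per-block AR(1) latent correlations, and the physical/genetic positions
#' (constant recombination rate `cm_per_mb`).
#'
#' @param p_snps Number of cis-SNPs (default 877).
#' @param block_size SNPs per LD block (default 20).
#' @param rho_range Range of per-block AR(1) correlations, drawn uniformly
#'   (default `c(0.2, 0.9)`); each must lie in (-1, 1).
#' @param maf_range Range of per-SNP target MAFs, drawn uniformly (default
#'   `c(0.01, 0.5)`).
#' @param spacing_bp Distance between adjacent SNPs in bp (default 2400,
#'   877 SNPs then span about 2.1 Mb).
#' @param cm_per_mb Recombination rate (default 1 cM/Mb, the genome-wide
#'   human average).
#' @param chrom,base_pos Chromosome label and first SNP position.
#' @param seed Optional RNG seed for the drawn MAFs and correlations.
#' @return An object of class `genotype_model`.
#' @export
genotype_model <- function(p_snps = 877, block_size = 20,
                           rho_range = c(0.2, 0.9),
                           maf_range = c(0.01, 0.5), spacing_bp = 2400,
                           cm_per_mb = 1, chrom = "1", base_pos = 1e6,
                           seed = NULL) {
  if (any(abs(rho_range) >= 1))
    stop("AR(1) correlations must lie in (-1, 1) for a positive-definite block")
  if (maf_range[1] < 0.01 || maf_range[2] > 0.5)
    stop("maf_range must lie within [0.01, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  n_blocks <- ceiling(p_snps / block_size)
  rhos <- runif(n_blocks, rho_range[1], rho_range[2])
  mafs <- runif(p_snps, maf_range[1], maf_range[2])
  pos <- base_pos + (seq_len(p_snps) - 1) * spacing_bp
  snps <- data.frame(
    snp_id = sprintf("snp%04d", seq_len(p_snps)), chrom = chrom, pos = pos,
    ref = "A", alt = "G", maf = mafs, cm = pos * cm_per_mb / 1e6,
    stringsAsFactors = FALSE)
  structure(list(p_snps = p_snps, block_size = block_size, rhos = rhos,
                 mafs = mafs, snps = snps), class = "genotype_model")
}

#' Simulate LD-structured genotypes
#'
#' Each of two haplotypes is a latent multivariate normal with block-AR(1)
#' correlation, thresholded at the normal quantile of the SNP's target MAF;
#' their sum gives genotypes in {0, 1, 2} whose counted (alt) allele has
#' expected frequency equal to the target MAF and whose local correlation
#' mirrors the latent blocks.
#'
#' @param n Number of samples.
#' @param model A [genotype_model()]; alternatively pass `p` and model
#'   arguments via `...` to draw a fresh one.
#' @param seed Optional RNG seed (genotypes are bit-reproducible given the
#'   model and seed).
#' @param ... Arguments forwarded to [genotype_model()] when `model` is
#'   missing.
#' @return A [reference_panel()] (the `genotype_model` is attached as
#'   attribute `"model"`).
#' @export
simulate_genotypes <- function(n, model = NULL, seed = NULL, ...) {
  if (is.null(model)) model <- genotype_model(...)
  if (!is.null(seed)) set.seed(seed)
  g <- gen_geno_matrix(n, model)
  panel <- reference_panel(sprintf("sample%06d", seq_len(n)), g, model$snps)
  attr(panel, "model") <- model
  panel
}

# Core generator shared by the public wrapper and the experiment fast path.
gen_geno_matrix <- function(n, model) {
  p <- model$p_snps
  g <- matrix(0, n, p)
  thr <- qnorm(model$mafs)
  start <- 1L
  for (b in seq_along(model$rhos)) {
    k <- min(model$block_size, p - start + 1L)
    cols <- start:(start + k - 1L)
    L <- chol(model$rhos[b]^abs(outer(seq_len(k), seq_len(k), "-")))
    for (hap in 1:2) {
      z <- matrix(rnorm(n * k), n, k) %*% L
      for (j in seq_len(k)) {
        cj <- cols[j]
        g[, cj] <- g[, cj] + (z[, j] < thr[cj])
      }
    }
    start <- start + k
  }
  colnames(g) <- model$snps$snp_id
  g
}

# Standardized genotypes without building a reference_panel (experiments).
# A SNP that happens to be monomorphic in a small cohort carries no
# information there; its column is left at zero rather than erroring.
sim_geno_std <- function(n, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- gen_geno_matrix(n, model)
  ctr <- colMeans(g)
  g <- sweep(g, 2, ctr, "-")
  v <- colMeans(g^2)
  v[v == 0] <- 1
  sweep(g, 2, sqrt(v), "/")
}

#' Simulate expression from standardized genotypes
#'
#' Picks `ceiling(p_causal * p)` causal SNPs uniformly at random, draws
#' their effects from N(0, 1) (zero elsewhere), rescales the effect vector
#' so the realized variance of the genetic component `X w` equals `h_e2`,
#' and adds N(0, 1 - h_e2) noise, so total expression variance is about 1.
#'
#' @param X Standardized genotype matrix (samples x SNPs).
#' @param h_e2 Expression heritability in `[0, 1)`.
#' @param p_causal Causal SNP fraction in `(0, 1]`.
#' @param seed Optional RNG seed.
#' @return List with `expression`, the rescaled effect vector `w` (reusable
#'   on other cohorts of the same gene) and `causal` indices.
#' @export
simulate_expression <- function(X, h_e2, p_causal, seed = NULL) {
  if (h_e2 < 0 || h_e2 >= 1) stop("h_e2 must lie in [0, 1)")
  if (p_causal <= 0 || p_causal > 1) stop("p_causal must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  if (p_causal * p < 1)
    warning("p_causal * p < 1; using a single causal SNP")
  n_causal <- max(1L, ceiling(p_causal * p))
  causal <- sample.int(p, n_causal)
  w <- numeric(p)
  if (h_e2 > 0) {
    w[causal] <- rnorm(n_causal)
    genetic <- drop(X %*% w)
    w <- w * sqrt(h_e2) / sd(genetic)
  }
  list(expression = drop(X %*% w) + rnorm(n, 0, sqrt(1 - h_e2)),
       w = w, causal = causal)
}

# Expression on a new cohort reusing an already-rescaled effect vector.
expression_from_weights <- function(X, w, h_e2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  drop(X %*% w) + rnorm(nrow(X), 0, sqrt(1 - h_e2))
}

#' Simulate a phenotype driven by expression
#'
#' `Y = beta * E + eps_p` with `eps_p ~ N(0, 1 - h_p2)`. By default `beta`
#' is rescaled so the realized variance of `beta * E` equals `h_p2` (the
#' fraction of phenotypic variance explained by expression). The
#' alternative `mode = "genetic"` scales against the genetic component of
#' expression instead (`var(beta * X w) = h_p2`).
#'
#' @param expression Expression vector `E`.
#' @param h_p2 Phenotypic heritability in `[0, 1)`.
#' @param seed Optional RNG seed.
#' @param genetic Genetic component `X w` (required for
#'   `mode = "genetic"`).
#' @param mode Scaling convention, `"expression"` (default) or
#'   `"genetic"`.
#' @return List with `y` and the rescaled `beta`.
#' @export
simulate_phenotype <- function(expression, h_p2, seed = NULL,
                               genetic = NULL,
                               mode = c("expression", "genetic")) {
  mode <- match.arg(mode)
  if (h_p2 < 0 || h_p2 >= 1) stop("h_p2 must lie in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(expression)
  beta <- 0
  if (h_p2 > 0) {
    target <- if (mode == "expression") expression else genetic
    if (is.null(target)) stop("mode = 'genetic' needs the genetic component")
    if (sd(target) == 0)
      stop("zero-variance expression with h_p2 > 0")
    beta <- sqrt(h_p2) / sd(target)
  }
  list(y = beta * expression + rnorm(n, 0, sqrt(1 - h_p2)), beta = beta)
}

# Per-SNP marginal z-scores (t-statistics of simple regression on each
# standardized SNP), vectorized; returns list(z, r).
marginal_z <- function(X_std, y) {
  n <- nrow(X_std)
  if (n < 3) stop("need at least 3 samples for marginal regression")
  yc <- y - mean(y)
  sy <- sqrt(mean(yc^2))
  if (sy == 0) stop("outcome has zero variance")
  r <- drop(crossprod(X_std, yc)) / (n * sy)
  r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  list(z = r * sqrt((n - 2) / (1 - r^2)), r = r)
}

#' Derive summary statistics from individual-level data
#'
#' Regresses the outcome on each standardized SNP separately and reports
#' the coefficient z-statistic, the per-SNP route by which real
#' summary-level releases are produced.
#'
#' @param panel A [reference_panel()] (or a genotype matrix plus `snps`).
#' @param y Outcome vector: expression for `type = "eqtl"`, trait for
#'   `type = "gwas"`.
#' @param type `"eqtl"` or `"gwas"`.
#' @param gene_id Gene label for eQTL output.
#' @param snps SNP metadata when `panel` is a bare matrix.
#' @return An [eqtl_summary()] (with `N_j = n` for every SNP) or a
#'   [gwas_summary()].
#' @export
make_summary <- function(panel, y, type = c("eqtl", "gwas"),
                         gene_id = "GENE", snps = NULL) {
  type <- match.arg(type)
  if (inherits(panel, "reference_panel")) {
    snps <- panel$snps
    X <- standardize_genotypes(panel)
  } else {
    X <- standardize_genotypes(panel)
    if (is.null(snps)) stop("snps metadata required for a bare matrix")
  }
  mz <- marginal_z(X, y)
  if (type == "eqtl")
    eqtl_summary(gene_id, snps, mz$z, rep(nrow(X), ncol(X)))
  else gwas_summary(snps, mz$z)
}
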