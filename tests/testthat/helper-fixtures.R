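# Shared fixture builders. Everything is generated in code; no binary data
# ships with the package.

# A small deterministic panel with hand-chosen genotypes.
toy_panel <- function(n = 6, snp_ids = c("rs1", "rs2", "rs3"),
                      ref = c("A", "C", "G"), alt = c("G", "T", "A"),
                      pos = c(1e6, 2e6, 3e6), chrom = "1",
                      genotypes = NULL, maf = NA, cm = NULL) {
  p <- length(snp_ids)
  if (is.null(genotypes)) {
    set.seed(42)
    genotypes <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
  }
  snps <- data.frame(snp_id = snp_ids, chrom = chrom, pos = pos,
                     ref = ref, alt = alt, stringsAsFactors = FALSE)
  if (!all(is.na(maf))) snps$maf <- maf
  if (!is.null(cm)) snps$cm <- cm
  reference_panel(sprintf("s%02d", seq_len(nrow(genotypes))), genotypes, snps)
}

# Simulated panel from the latent-Gaussian generator.
sim_panel <- function(n = 200, p = 30, seed = 1, rho = c(0.2, 0.9),
                      maf = c(0.05, 0.5)) {
  model <- genotype_model(p_snps = p, block_size = min(10, p),
                          rho_range = rho, maf_range = maf, seed = seed)
  simulate_genotypes(n, model, seed = seed + 1)
}

# Write an eQTL summary fixture file; rows is a data frame with columns
# SNP, Gene, SNPChr, SNPPos, AssessedAllele, OtherAllele, Zscore, NrSamples.
write_eqtl_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

eqtl_rows <- function(snp = paste0("rs", 1:5),
                      gene = c("GENE1", "GENE1", "GENE1", "GENE2", "GENE2"),
                      pos = seq(1.5e6, 2.5e6, length.out = 5),
                      alt = c("G", "T", "A", "G", "C"),
                      ref = c("A", "C", "G", "A", "T"),
                      z = c(2, -1, 0.5, 3, -2),
                      n = c(100, 200, 150, 120, 130)) {
  data.frame(SNP = snp, Gene = gene, SNPChr = "1", SNPPos = pos,
             AssessedAllele = alt, OtherAllele = ref, Zscore = z,
             NrSamples = n, stringsAsFactors = FALSE)
}

toy_gene <- function(gene_id = "GENE1", chrom = "1", tss = 2e6, tes = 2.01e6)
  gene_annotation(gene_id, chrom, tss, tes)

# In-sample marginal correlations and LD from individual-level data, the
# exact statistics under which summary-based and individual-level fits
# coincide.
insample_stats <- function(X, y) {
  Xs <- standardize_genotypes(X)
  n <- nrow(Xs)
  yc <- y - mean(y)
  r <- drop(crossprod(Xs, yc)) / (n * sqrt(mean(yc^2)))
  R <- crossprod(Xs) / n
  diag(R) <- 1
  list(X = Xs, r = r, R = R, n = n)
}

# Closed-form coordinate updates under identity LD, computed here from the
# univariate minimizer of (1+theta) w^2 - 2 z w + 2 J(w) as an independent
# oracle for the C++ solver.
soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
univariate_solution <- function(z, spec) {
  th <- spec$theta; lam <- spec$lambda; g <- spec$gamma; a <- spec$alpha
  switch(spec$family,
    lasso = soft(z, lam) / (1 + th),
    elastic_net = soft(z, a * lam) / (1 + th + (1 - a) * lam),
    mcp = ifelse(abs(z) <= g * lam * (1 + th),
                 soft(z, lam) / (1 + th - 1 / g), z / (1 + th)),
    scad = ifelse(abs(z) <= lam * (2 + th), soft(z, lam) / (1 + th),
             ifelse(abs(z) <= g * lam * (1 + th),
                    soft(z, g * lam / (g - 1)) / (1 + th - 1 / (g - 1)),
                    z / (1 + th))),
    mnet = {
      d <- 1 + th + (1 - a) * lam
      ifelse(abs(z) <= g * a * lam * d,
             soft(z, a * lam) / (d - 1 / g), z / d)
    })
}

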