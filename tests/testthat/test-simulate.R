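test_that("synthetic genotypes hit target frequencies, local LD, and are seed-reproducible", {
  model <- genotype_model(p_snps = 30, block_size = 10,
                          rho_range = c(0.5, 0.5), maf_range = c(0.1, 0.4),
                          seed = 7)
  panel <- simulate_genotypes(10000, model, seed = 8)
  g <- panel$genotypes
  expect_true(all(g %in% 0:2))
  # realized allele frequency within 3 binomial SEs of the target
  af <- colMeans(g) / 2
  se <- sqrt(model$mafs * (1 - model$mafs) / (2 * 10000))
  expect_true(all(abs(af - model$mafs) < 3.5 * se))
  # adjacent-pair genotype correlation tracks the dichotomized latent
  # correlation; for equal thresholds near MAF 0.5 the exact value is the
  # arcsine transform (2/pi) asin(rho), the attainable ceiling for a
  # threshold model (the latent rho itself is not attainable)
  adj <- vapply(seq_len(29), function(j)
    if (j %% 10 == 0) NA_real_ else cor(g[, j], g[, j + 1]), numeric(1))
  expect_lt(abs(mean(adj, na.rm = TRUE) - 2 / pi * asin(0.5)), 0.08)
  # and it increases with the latent correlation
  m9 <- genotype_model(p_snps = 30, block_size = 10,
                       rho_range = c(0.9, 0.9), maf_range = c(0.1, 0.4),
                       seed = 7)
  g9 <- simulate_genotypes(4000, m9, seed = 8)$genotypes
  adj9 <- vapply(seq_len(29), function(j)
    if (j %% 10 == 0) NA_real_ else cor(g9[, j], g9[, j + 1]), numeric(1))
  expect_gt(mean(adj9, na.rm = TRUE), mean(adj, na.rm = TRUE))
  # determinism
  again <- simulate_genotypes(10000, model, seed = 8)
  expect_identical(g, again$genotypes)
  # invalid LD spec is refused
  expect_error(genotype_model(rho_range = c(0.2, 1)), "positive-definite")
})

test_that("expression generation realizes the requested heritability exactly by rescaling", {
  model <- genotype_model(p_snps = 877, block_size = 20, seed = 9)
  X <- standardize_genotypes(simulate_genotypes(400, model, seed = 10))
  # causal count is the ceiling of p_causal * p
  sim <- simulate_expression(X, 0.1, 0.2, seed = 11)
  expect_equal(sum(sim$w != 0), 176)
  expect_equal(var(drop(X %*% sim$w)), 0.1, tolerance = 1e-12)
  # h_e2 = 0: pure noise, all-zero effects
  sim0 <- simulate_expression(X, 0, 0.2, seed = 12)
  expect_true(all(sim0$w == 0))
  # realized variance ratio concentrates on h_e2 across replicates
  Xs <- standardize_genotypes(simulate_genotypes(5000,
    genotype_model(p_snps = 60, block_size = 12, seed = 13), seed = 14))
  ratio <- vapply(1:40, function(i) {
    s <- simulate_expression(Xs, 0.1, 0.1, seed = 100 + i)
    var(drop(Xs %*% s$w)) / var(s$expression)
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 0.1), 0.005)
  # total variance is about 1 at large n
  s <- simulate_expression(Xs, 0.1, 0.1, seed = 15)
  expect_lt(abs(var(s$expression) - 1), 0.02)
  # sub-single causal count warns and uses one SNP
  expect_warning(sim1 <- simulate_expression(Xs[, 1:5], 0.1, 0.01, seed = 16),
                 "single causal")
  expect_equal(sum(sim1$w != 0), 1)
})

test_that("phenotype generation follows Y = beta E + noise at the requested h_p2", {
  set.seed(21)
  e <- rnorm(10000)
  ph <- simulate_phenotype(e, 0.2, seed = 22)
  expect_lt(abs(var(ph$beta * e) / var(ph$y) - 0.2), 0.01)
  expect_lt(abs(var(ph$y) - 1), 0.02)
  # h_p2 = 0: no dependence
  ph0 <- simulate_phenotype(e, 0, seed = 23)
  expect_equal(ph0$beta, 0)
  expect_lt(abs(cor(ph0$y, e)), 0.05)
  # determinism and degenerate input
  expect_identical(simulate_phenotype(e, 0.2, seed = 22)$y, ph$y)
  expect_error(simulate_phenotype(rep(1, 100), 0.5, seed = 1), "variance")
  # genetic-component scaling mode
  g <- 0.5 * e
  phg <- simulate_phenotype(e, 0.2, seed = 24, genetic = g,
                            mode = "genetic")
  expect_lt(abs(var(phg$beta * g) / 1 - 0.2), 0.01)
})

test_that("derived summary statistics behave like per-SNP regression z-scores", {
  model <- genotype_model(p_snps = 50, block_size = 10, seed = 31,
                          maf_range = c(0.1, 0.5))
  panel <- simulate_genotypes(10000, model, seed = 32)
  X <- standardize_genotypes(panel)
  # perfect predictor: huge z, marginal correlation essentially 1
  y1 <- X[, 1]
  tab1 <- make_summary(panel, y1, "eqtl")
  expect_gt(abs(tab1$z[1]), 100)
  expect_gt(standardized_marginal_effects(tab1)[1], 0.999)
  expect_true(all(tab1$n == 10000))
  # independent outcome: z approximately standard normal
  model2 <- genotype_model(p_snps = 500, block_size = 1,
                           rho_range = c(0.2, 0.2), seed = 33)
  panel2 <- simulate_genotypes(1000, model2, seed = 34)
  set.seed(35)
  tab2 <- make_summary(panel2, rnorm(1000), "eqtl")
  expect_gt(stats::ks.test(tab2$z, "pnorm")$p.value, 0.01)
  # round-trip identity: z-based marginal effects match sample correlations
  set.seed(36)
  y3 <- drop(X[, 1:3] %*% c(.2, -.1, .1)) + rnorm(10000)
  tab3 <- make_summary(panel, y3, "eqtl")
  expect_lt(max(abs(standardized_marginal_effects(tab3) -
                      drop(cor(X, y3)))), 1e-3)
  # monomorphic SNP is an error
  mono <- panel
  mono$genotypes[, 2] <- 1
  expect_error(make_summary(mono, y3, "eqtl"), "snp0002")
})

test_that("experiments are deterministic given the seed", {
  cfg <- sim_config(n_train = 600, n_tune = 120, n_test = 300, n_gwas = 300,
                    p_snps = 30, h_e2 = 0.4, p_causal = 0.2, h_p2 = 0.5,
                    n_replicates = 2, seed = 5,
                    training = training_config(n_lambda = 8,
                                               lambda_min_ratio = 0.05,
                                               theta_grid = 0.1,
                                               families = c("lasso", "mcp")))
  a <- run_accuracy_experiment(cfg, include_oracle = FALSE)
  b <- run_accuracy_experiment(cfg, include_oracle = FALSE)
  expect_identical(a$results, b$results)
  pw <- run_power_experiment(cfg)
  pw2 <- run_power_experiment(cfg)
  expect_identical(pw$results, pw2$results)
  expect_true(all(pw$results$combined_p > 0 & pw$results$combined_p <= 1,
                  na.rm = TRUE))
  t1 <- run_type1_experiment(cfg, n_weight_sets = 2, n_null = 50)
  t2 <- run_type1_experiment(cfg, n_weight_sets = 2, n_null = 50)
  expect_identical(t1$p_values, t2$p_values)
})
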