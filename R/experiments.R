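# Simulation experiments: expression-imputation accuracy, TWAS power, and
# type-I error. Each replicate draws a fresh gene (LD model + causal
# architecture), trains from the training cohort's derived summary
# statistics, tunes and validates on independent cohorts, and (for
# power/type-I) tests against a simulated GWAS cohort.

#' Simulation configuration
#'
#' Defaults reproduce the study conditions of the main simulation: a gene
#' with 877 cis-SNPs, an expression reference panel of 31,684 samples,
#' tuning and test cohorts of 369 and 10,000, and significance at
#' 0.05 / 20,000 = 2.5e-6.
#'
#' @param n_train,n_tune,n_test Cohort sizes (defaults 31684, 369, 10000).
#' @param n_gwas GWAS cohort size for power/type-I runs (default `n_test`).
#' @param p_snps Number of cis-SNPs (default 877).
#' @param h_e2 Expression heritability (default 0.1).
#' @param h_p2 Phenotypic heritability, variance of phenotype explained by
#'   expression (default 0.2).
#' @param p_causal Causal SNP fraction (default 0.05).
#' @param block_size,rho_range,maf_range LD model, see [genotype_model()].
#' @param n_replicates Number of replicates (default 100).
#' @param seed Global seed; replicate r uses stream `seed + 13 * r`.
#' @param sig_threshold Genome-wide significance level (default 2.5e-6).
#' @param r2_min Model admission threshold (default 0.005).
#' @param hp2_mode Phenotype scaling convention, see [simulate_phenotype()].
#' @param shrink Apply the shrinkage LD estimator in the summary arm
#'   (default TRUE).
#' @param training A [training_config()]. The simulation default uses a
#'   25-point lambda path down to 0.02 of lambda_max and ridge grid
#'   `{0, 0.1, 0.4}`: the tuning optimum sits well inside that range and
#'   the lighter grid keeps replicate counts affordable.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_train = 31684, n_tune = 369, n_test = 10000,
                       n_gwas = n_test, p_snps = 877, h_e2 = 0.1,
                       h_p2 = 0.2, p_causal = 0.05, block_size = 20,
                       rho_range = c(0.2, 0.9), maf_range = c(0.01, 0.5),
                       n_replicates = 100, seed = 1,
                       sig_threshold = 2.5e-6, r2_min = 0.005,
                       hp2_mode = "expression", shrink = TRUE,
                       training = training_config(n_lambda = 25,
                                                  lambda_min_ratio = 0.02,
                                                  theta_grid = c(0, 0.1, 0.4))) {
  stopifnot(h_e2 >= 0, h_e2 <= 1, h_p2 >= 0, h_p2 <= 1,
            p_causal > 0, p_causal <= 1,
            n_train >= 2, n_tune >= 2, n_test >= 2)
  structure(list(n_train = n_train, n_tune = n_tune, n_test = n_test,
                 n_gwas = n_gwas, p_snps = p_snps, h_e2 = h_e2, h_p2 = h_p2,
                 p_causal = p_causal, block_size = block_size,
                 rho_range = rho_range, maf_range = maf_range,
                 n_replicates = n_replicates, seed = seed,
                 sig_threshold = sig_threshold, r2_min = r2_min,
                 hp2_mode = hp2_mode, shrink = shrink, training = training),
            class = "sim_config")
}

rep_seed <- function(seed, r) (seed + 13 * r) %% 2147483647L

# One training replicate: simulate the gene, train the summary-based models
# (and optionally the individual-level oracle arm), tune, validate.
# Returns the selected-model test R2 for each arm plus what the
# power/type-I stages need.
train_replicate <- function(config, r, include_oracle = FALSE,
                            keep_weights = FALSE) {
  s <- rep_seed(config$seed, r)
  model <- genotype_model(p_snps = config$p_snps,
                          block_size = config$block_size,
                          rho_range = config$rho_range,
                          maf_range = config$maf_range, seed = s)
  X_tr <- sim_geno_std(config$n_train, model, seed = s + 1)
  sim <- simulate_expression(X_tr, config$h_e2, config$p_causal, seed = s + 2)
  mz <- marginal_z(X_tr, sim$expression)
  n <- nrow(X_tr)
  r_tilde <- mz$z / sqrt(n - 1 + mz$z^2) # summary-level marginal effects
  R_raw <- ld_matrix(model$snps$snp_id,
                     local({
                       v <- crossprod(X_tr) / n
                       v <- (v + t(v)) / 2; diag(v) <- 1
                       v[v > 1] <- 1; v[v < -1] <- -1; v
                     }))
  R_tilde <- if (config$shrink) shrink_ld(R_raw, model$snps$cm) else R_raw
  X_tu <- sim_geno_std(config$n_tune, model, seed = s + 3)
  e_tu <- expression_from_weights(X_tu, sim$w, config$h_e2, seed = s + 4)
  tuning <- list(genotypes = X_tu, expression = e_tu)
  X_te <- sim_geno_std(config$n_test, model, seed = s + 5)
  e_te <- expression_from_weights(X_te, sim$w, config$h_e2, seed = s + 6)

  score <- function(fits) {
    fits <- lapply(fits, function(m) {
      m$r2_testing <- r_squared(drop(X_te %*% m$w_hat), e_te)
      m
    })
    tun <- vapply(fits, `[[`, numeric(1), "r2_tuning")
    list(fits = fits, r2_selected = fits[[which.max(tun)]]$r2_testing,
         family = names(fits)[which.max(tun)])
  }
  fits_sum <- score(fit_gene_marginal("SIMGENE", model$snps, r_tilde,
                                      R_tilde, tuning, config$training))
  out <- list(replicate = r, seed = s,
              r2_summary = fits_sum$r2_selected,
              family = fits_sum$family)
  if (include_oracle) {
    fits_or <- score(fit_gene_marginal("SIMGENE", model$snps, mz$r, R_raw,
                                       tuning, config$training))
    out$r2_oracle <- fits_or$r2_selected
  }
  if (keep_weights) {
    admitted <- Filter(function(m) m$r2_testing >= config$r2_min,
                       fits_sum$fits)
    out$admitted <- admitted
    out$model <- model
    out$w_true <- sim$w
    out$V <- R_tilde
  }
  out
}

#' Expression-imputation accuracy experiment
#'
#' Per replicate: simulate a gene, derive eQTL summary statistics from the
#' training cohort, fit all penalty families against the shrinkage LD
#' estimator, select the best model by tuning R-squared, and report its
#' squared correlation with observed expression in the held-out test
#' cohort. Optionally fits the individual-level arm in parallel (exact
#' in-sample marginal correlations and raw LD), the benchmark the
#' summary-based fit should match.
#'
#' @param config A [sim_config()].
#' @param include_oracle Also run the individual-level arm (default TRUE).
#' @return List with the per-replicate data frame `results`, `mean_r2` and
#'   (when requested) `mean_r2_oracle`.
#' @export
run_accuracy_experiment <- function(config = sim_config(),
                                    include_oracle = TRUE) {
  rows <- lapply(seq_len(config$n_replicates), function(r) {
    res <- train_replicate(config, r, include_oracle = include_oracle)
    data.frame(replicate = r, r2_summary = res$r2_summary,
               family = res$family,
               r2_oracle = if (include_oracle) res$r2_oracle else NA_real_)
  })
  results <- do.call(rbind, rows)
  out <- list(results = results, mean_r2 = mean(results$r2_summary),
              config = config)
  if (include_oracle) out$mean_r2_oracle <- mean(results$r2_oracle)
  out
}

# Burden + Cauchy on one simulated GWAS cohort given admitted models.
combined_p_for_cohort <- function(admitted, z, V) {
  if (!length(admitted)) return(NA_real_)
  res <- lapply(admitted, function(m) burden_test(m$w_hat, z, V))
  ps <- vapply(res, `[[`, numeric(1), "p_value")
  r2 <- vapply(admitted, `[[`, numeric(1), "r2_testing")
  ps <- pmin(pmax(ps, 1e-300), 1 - 1e-16)
  cauchy_combine(ps, r2)
}

#' TWAS power experiment
#'
#' Per replicate: train and validate models as in
#' [run_accuracy_experiment()], then simulate an independent GWAS cohort
#' (expression from the same causal effects, phenotype at heritability
#' `h_p2`), derive GWAS z-scores, and run the burden + Cauchy combination
#' over the admitted models. Power is the fraction of replicates with a
#' combined p-value below `sig_threshold`; replicates with no admitted
#' model count as non-rejections.
#'
#' @param config A [sim_config()].
#' @return List with `power`, a binomial 95% CI, and the per-replicate
#'   data frame `results`.
#' @export
run_power_experiment <- function(config = sim_config()) {
  rows <- lapply(seq_len(config$n_replicates), function(r) {
    res <- train_replicate(config, r, keep_weights = TRUE)
    s <- res$seed
    X_g <- sim_geno_std(config$n_gwas, res$model, seed = s + 7)
    e_g <- expression_from_weights(X_g, res$w_true, config$h_e2, seed = s + 8)
    phen <- simulate_phenotype(e_g, config$h_p2, seed = s + 9,
                               genetic = drop(X_g %*% res$w_true),
                               mode = config$hp2_mode)
    z <- marginal_z(X_g, phen$y)$z
    p <- combined_p_for_cohort(res$admitted, z, res$V)
    data.frame(replicate = r, n_admitted = length(res$admitted),
               r2_summary = res$r2_summary, combined_p = p,
               reject = !is.na(p) & p < config$sig_threshold)
  })
  results <- do.call(rbind, rows)
  k <- sum(results$reject); n <- nrow(results)
  se <- sqrt(max(k / n * (1 - k / n), 0) / n)
  list(power = k / n, ci = c(max(0, k / n - 1.96 * se),
                             min(1, k / n + 1.96 * se)),
       results = results, config = config)
}

#' Type-I error experiment
#'
#' Trains `n_weight_sets` independent weight sets, then reuses each across
#' `n_null` null GWAS replicates (phenotype independent of genotypes,
#' beta = 0) and reports the empirical rejection rate of the combined
#' p-value at each `alpha_level`. Weight sets with no admitted model are
#' skipped and counted.
#'
#' @param config A [sim_config()].
#' @param n_weight_sets Number of trained weight sets (default 100).
#' @param n_null Null GWAS replicates per weight set (default 500).
#' @param alpha_levels Nominal levels to evaluate.
#' @return List with `rates` (named by alpha), `n_reps` (null replicates
#'   contributing), `n_skipped` weight sets, and the per-null p-values.
#' @export
run_type1_experiment <- function(config = sim_config(),
                                 n_weight_sets = 100, n_null = 500,
                                 alpha_levels = c(0.05, 0.01, 1e-3)) {
  pvals <- c(); skipped <- 0L
  for (ws in seq_len(n_weight_sets)) {
    res <- train_replicate(config, ws, keep_weights = TRUE)
    if (!length(res$admitted)) { skipped <- skipped + 1L; next }
    s <- res$seed
    X_g <- sim_geno_std(config$n_gwas, res$model, seed = s + 7)
    set.seed(s + 8)
    n <- nrow(X_g)
    Y <- matrix(rnorm(n * n_null), n, n_null)
    Yc <- sweep(Y, 2, colMeans(Y), "-")
    sy <- sqrt(colMeans(Yc^2))
    Rm <- crossprod(X_g, Yc) / n # p x n_null, = cor * sy
    Rm <- sweep(Rm, 2, sy, "/")
    Rm <- pmin(pmax(Rm, -(1 - 1e-12)), 1 - 1e-12)
    Z <- Rm * sqrt((n - 2) / (1 - Rm^2))
    V <- res$V$values
    W <- vapply(res$admitted, `[[`, numeric(nrow(V)), "w_hat")
    W <- matrix(W, nrow = nrow(V))
    denom <- sqrt(colSums((V %*% W) * W))
    Zt <- t(crossprod(W, Z) / denom) # n_null x n_models
    Pm <- 2 * pnorm(-abs(Zt))
    Pm <- pmin(pmax(Pm, 1e-300), 1 - 1e-16)
    r2 <- vapply(res$admitted, `[[`, numeric(1), "r2_testing")
    pvals <- c(pvals, apply(Pm, 1, cauchy_combine, r2_weights = r2))
  }
  rates <- vapply(alpha_levels, function(a) mean(pvals < a), numeric(1))
  list(rates = setNames(rates, paste0("alpha_", alpha_levels)),
       n_reps = length(pvals), n_skipped = skipped, p_values = pvals,
       config = config)
}
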