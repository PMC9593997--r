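test_that("marginal effect standardization follows z / sqrt(N - 1 + z^2)", {
  tab <- list(z = c(0, 2, 1e8, -1e8), n = c(50, 101, 100, 100))
  r <- standardized_marginal_effects(tab)
  expect_equal(r[1], 0)
  expect_equal(r[2], 2 / sqrt(104))
  expect_equal(r[2], 0.19612, tolerance = 1e-4)
  expect_true(all(abs(r) < 1))
  expect_gt(r[3], 0.999999)
  expect_error(standardized_marginal_effects(list(z = c(1, NA), n = c(5, 5))),
               "finite")
})

test_that("marginal effects from z-scores track the sample correlation", {
  # simulate a dataset whose per-SNP t is computed directly, then compare
  # the z-based reconstruction with the realized sample correlations
  set.seed(14)
  panel <- sim_panel(n = 1001, p = 12, seed = 14)
  X <- standardize_genotypes(panel)
  y <- X[, 1] * 0.2 + rnorm(1001)
  tab <- make_summary(panel, y, "eqtl")
  r_hat <- standardized_marginal_effects(tab)
  r_direct <- drop(cor(X, y))
  expect_equal(r_hat, r_direct, tolerance = 2e-3, ignore_attr = TRUE)
})

test_that("objective is zero at w = 0 and consistent with the update rule", {
  pen <- penalty_spec("lasso", 0.2)
  expect_equal(sq_objective(numeric(3), c(.5, .1, -.3), diag(3), pen), 0)
  # p = 1 example: w'Rw - 2 w'r + 2 lambda |w| = 0.09 - 0.30 + 0.12
  expect_equal(sq_objective(0.3, 0.5, matrix(1), pen), -0.09)
  # solver solution never scores above the zero vector
  set.seed(3)
  for (fam in c("lasso", "elastic_net", "mcp", "scad", "mnet")) {
    st <- insample_stats(sim_panel(n = 150, p = 10, seed = 21)$genotypes,
                         rnorm(150))
    spec <- penalty_spec(fam, 0.05, theta = 0.1)
    fit <- coordinate_descent(st$r, st$R, spec)
    expect_lte(sq_objective(fit$w, st$r, st$R, spec), 0)
  }
})

test_that("coordinate descent reproduces the closed forms under identity LD for every family", {
  r <- c(0.5, 0.1, -0.3)
  I3 <- diag(3)
  for (fam in c("lasso", "elastic_net", "mcp", "scad", "mnet")) {
    for (th in c(0, 1)) {
      spec <- penalty_spec(fam, 0.2, theta = th)
      fit <- coordinate_descent(r, I3, spec)
      expect_equal(fit$w, univariate_solution(r, spec), tolerance = 1e-10,
                   info = paste(fam, "theta", th))
    }
  }
  # the two printed LASSO cases
  expect_equal(coordinate_descent(r, I3, penalty_spec("lasso", 0.2))$w,
               c(0.3, 0, -0.1))
  expect_equal(coordinate_descent(r, I3,
                                  penalty_spec("lasso", 0.2, theta = 1))$w,
               c(0.15, 0, -0.05))
  # lambda at or above max|r| gives the all-zero lasso solution
  expect_equal(coordinate_descent(r, I3, penalty_spec("lasso", 0.5))$w,
               c(0, 0, 0))
})

test_that("each full sweep is non-increasing in the objective", {
  set.seed(8)
  panel <- sim_panel(n = 400, p = 15, seed = 31, rho = c(0.5, 0.9))
  y <- rnorm(400) + standardize_genotypes(panel)[, 3]
  st <- insample_stats(panel$genotypes, y)
  for (fam in c("lasso", "elastic_net", "mcp", "scad", "mnet")) {
    spec <- penalty_spec(fam, 0.03, theta = 0.2)
    obj <- vapply(1:6, function(k) {
      w <- suppressWarnings(
        coordinate_descent(st$r, st$R, spec, max_iter = k))$w
      sq_objective(w, st$r, st$R, spec)
    }, numeric(1))
    expect_true(all(diff(obj) <= 1e-12), info = fam)
  }
})

test_that("lambda paths are log-spaced from max|r| and handle degeneracy", {
  expect_equal(lambda_path(c(0.5, 0.1, -0.3), 3, 0.01), c(0.5, 0.05, 0.005))
  expect_equal(lambda_path(c(0, 0, 0)), 0)
  expect_equal(max(lambda_path(c(0.5, 0.1))), 0.5)
  expect_error(lambda_path(numeric(0)), "empty")
})

test_that("summary-based lasso matches glmnet on in-sample statistics across the path", {
  set.seed(19)
  panel <- sim_panel(n = 250, p = 20, seed = 41, rho = c(0.4, 0.8))
  X <- standardize_genotypes(panel)
  y <- drop(X[, c(2, 9)] %*% c(0.4, -0.3)) + rnorm(250)
  st <- insample_stats(panel$genotypes, y)
  lams <- lambda_path(st$r, 12, 0.05)
  ours <- vapply(lams, function(l)
    coordinate_descent(st$r, st$R, penalty_spec("lasso", l),
                       tol = 1e-10, max_iter = 5000)$w, numeric(20))
  # on the standardized outcome (variance 1, denominator n) glmnet's
  # objective RSS/(2n) + lambda ||w||_1 matches ours on the same lambda grid
  yc <- y - mean(y)
  ys <- yc / sqrt(mean(yc^2))
  gl <- glmnet::glmnet(st$X, ys, lambda = lams,
                       standardize = FALSE, intercept = FALSE,
                       thresh = 1e-14)
  expect_lt(max(abs(ours - as.matrix(gl$beta))), 1e-6)
})

test_that("grid fitting recovers signal, scores noise near zero and tolerates degenerate weights", {
  set.seed(23)
  model <- genotype_model(p_snps = 40, block_size = 10, seed = 51,
                          maf_range = c(0.05, 0.5))
  panel <- simulate_genotypes(1500, model, seed = 52)
  X <- standardize_genotypes(panel)
  sim <- simulate_expression(X, h_e2 = 0.3, p_causal = 0.1, seed = 53)
  tab <- make_summary(panel, sim$expression, "eqtl", gene_id = "G1")
  R <- sample_ld(panel)
  X_tune <- standardize_genotypes(simulate_genotypes(300, model, seed = 54))
  e_tune <- drop(X_tune %*% sim$w) + rnorm(300, 0, sqrt(0.7))
  cfg <- training_config(n_lambda = 15, theta_grid = c(0, 0.2),
                         lambda_min_ratio = 0.05)
  fits <- fit_gene(tab, R, list(genotypes = X_tune, expression = e_tune), cfg)
  expect_named(fits, c("lasso", "elastic_net", "mcp", "scad", "mnet"))
  for (m in fits) expect_gt(m$r2_tuning, 0)
  # pure-noise tuning expression scores near zero
  fits0 <- fit_gene(tab, R, list(genotypes = X_tune,
                                 expression = rnorm(300)), cfg)
  for (m in fits0) expect_lt(m$r2_tuning, 0.05)
  # all-zero weights give R2 = 0, never NaN
  expect_identical(r_squared(rep(0, 10), rnorm(10)), 0)
  # tuning sets below 10 samples are refused
  expect_error(fit_gene(tab, R, list(genotypes = X_tune[1:5, ],
                                     expression = e_tune[1:5]), cfg),
               "10")
})

test_that("validation fills testing R2 and admits at the boundary", {
  set.seed(29)
  model <- genotype_model(p_snps = 12, block_size = 6, seed = 61)
  X_test <- standardize_genotypes(simulate_genotypes(400, model, seed = 62))
  w <- c(0.4, rep(0, 11))
  e_test <- drop(X_test %*% w) + rnorm(400)
  m <- weight_model("G1", model$snps, w, penalty_spec("lasso", 0.1),
                    r2_tuning = 0.1)
  testing <- list(genotypes = X_test, expression = e_test)
  scored <- validate_models(list(m), testing, r2_min = 0)
  r2 <- scored[[1]]$r2_testing
  expect_gt(r2, 0)
  # boundary inclusive: threshold exactly at the achieved R2 retains it
  expect_length(validate_models(list(m), testing, r2_min = r2), 1L)
  # just above the achieved R2 drops it
  expect_length(validate_models(list(m), testing, r2_min = r2 + 1e-12), 0L)
  expect_length(validate_models(list(), testing), 0L)
})

test_that("null R2 threshold matches the Beta quantile and its chi-square approximation", {
  thr <- cramer_r2_threshold(34, 31684, 0.05 / 16884)
  expect_equal(thr, qbeta(1 - 0.05 / 16884, 16.5, 15825))
  # Wilson-Hilferty chi-square approximation as an independent oracle:
  # R2 ~ chisq_{p-1} / (n - 1) under the null for small R2
  df <- 33
  zq <- qnorm(1 - 0.05 / 16884)
  chi <- df * (1 - 2 / (9 * df) + zq * sqrt(2 / (9 * df)))^3
  expect_equal(thr, chi / (31684 - 1), tolerance = 0.05)
  # limits and input validation: threshold decreases toward 0 as alpha -> 1
  thrs <- vapply(c(1e-6, 0.05, 0.5, 0.999999), function(a)
    cramer_r2_threshold(34, 31684, a), numeric(1))
  expect_true(all(diff(thrs) < 0))
  expect_lt(thrs[4], 1e-3)
  expect_error(cramer_r2_threshold(1, 100, 0.05), "n > p")
  expect_error(cramer_r2_threshold(10, 5, 0.05), "n > p")
  expect_error(cramer_r2_threshold(10, 100, 1.5), "alpha")
})

test_that("causal effects are recovered with positive correlation", {
  hits <- vapply(1:5, function(i) {
    model <- genotype_model(p_snps = 60, block_size = 12, seed = 70 + i)
    X <- standardize_genotypes(simulate_genotypes(3000, model,
                                                  seed = 170 + i))
    sim <- simulate_expression(X, h_e2 = 0.2, p_causal = 0.1,
                               seed = 270 + i)
    st <- list(r = drop(cor(X, sim$expression)), R = unname(crossprod(X) /
                                                              nrow(X)))
    diag(st$R) <- 1
    lams <- lambda_path(st$r, 10, 0.05)
    W <- sapply(lams, function(l)
      coordinate_descent(st$r, st$R, penalty_spec("lasso", l))$w)
    w_best <- W[, ncol(W)]
    cor(w_best[sim$causal], sim$w[sim$causal]) > 0
  }, logical(1))
  expect_true(all(hits))
})

test_that("weight databases round-trip through the text format", {
  model <- genotype_model(p_snps = 6, block_size = 3, seed = 81)
  m1 <- weight_model("G1", model$snps, c(0.5, 0, -0.2, 0, 0, 0),
                     penalty_spec("lasso", 0.1, theta = 0.2),
                     r2_tuning = 0.12, r2_testing = 0.08)
  m2 <- weight_model("G1", model$snps, c(0, 0.3, 0, 0, 0, 0.1),
                     penalty_spec("mcp", 0.05), r2_tuning = 0.10,
                     r2_testing = 0.06)
  wp <- tempfile(); mp <- tempfile()
  write_weight_models(list(m1, m2), wp, mp)
  back <- read_weight_models(wp, mp)
  expect_length(back, 2)
  expect_equal(back[[1]]$w_hat, c(0.5, -0.2))
  expect_equal(back[[1]]$snps$snp_id, model$snps$snp_id[c(1, 3)])
  expect_equal(back[[2]]$penalty$family, "mcp")
  expect_equal(back[[2]]$r2_testing, 0.06)
})
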