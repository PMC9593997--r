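# Per-gene expression prediction models fitted from summary statistics.
# The working objective, in the marginal-statistics parameterization, is
#   w' R w - 2 w' r + theta w'w + 2 J_lambda(w),
# minimized by cyclic coordinate descent (src/coord_descent.cpp). The
# factor 2 on the penalty makes the LASSO coordinate update the exact
# soft-threshold of the partial residual at lambda, scaled by 1/(1+theta);
# the other families use the matching exact univariate minimizers.

PENALTY_FAMILIES <- c(lasso = 1L, elastic_net = 2L, mcp = 3L,
                      scad = 4L, mnet = 5L)

#' Penalty specification
#'
#' @param family One of `"lasso"`, `"elastic_net"`, `"mcp"`, `"scad"`,
#'   `"mnet"`.
#' @param lambda Penalty level, `>= 0`.
#' @param gamma Concavity parameter (MCP/MNet: `> 1`, default 3;
#'   SCAD: `> 2`, default 3.7). Ignored by convex families.
#' @param alpha L1-mixing fraction in `(0, 1]` for elastic net / MNet
#'   (default 0.5); fixed at 1 otherwise.
#' @param theta Ridge coefficient `>= 0` added to the objective as
#'   `theta * w'w`; guarantees a unique minimizer when the LD matrix is
#'   rank-deficient.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(family = c("lasso", "elastic_net", "mcp", "scad",
                                    "mnet"),
                         lambda, gamma = NULL, alpha = NULL, theta = 0) {
  family <- match.arg(family)
  if (lambda < 0) stop("lambda must be >= 0")
  if (theta < 0) stop("theta must be >= 0")
  if (is.null(gamma)) gamma <- if (family == "scad") 3.7 else 3
  if (is.null(alpha)) alpha <- if (family %in% c("elastic_net", "mnet")) 0.5 else 1
  if (family == "scad" && gamma <= 2) stop("SCAD requires gamma > 2")
  if (family %in% c("mcp", "mnet") && gamma <= 1)
    stop(family, " requires gamma > 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(family = family, lambda = lambda, gamma = gamma,
                 alpha = alpha, theta = theta), class = "penalty_spec")
}

#' Training configuration
#'
#' @param n_lambda Number of penalty levels on the log-spaced path.
#' @param lambda_min_ratio Smallest lambda as a fraction of lambda_max.
#' @param theta_grid Ridge coefficients to scan.
#' @param alpha_grid L1 mixing fractions for elastic net / MNet.
#' @param gamma_mcp,gamma_scad Concavity defaults.
#' @param tol Convergence tolerance: maximum absolute coordinate change per
#'   sweep.
#' @param max_iter Maximum number of full sweeps.
#' @param r2_min Validation R-squared admission threshold (default 0.005).
#' @param families Penalty families to fit.
#' @return An object of class `training_config`.
#' @export
training_config <- function(n_lambda = 50, lambda_min_ratio = 0.01,
                            theta_grid = c(0, 0.1, 0.2, 0.4, 0.8),
                            alpha_grid = 0.5, gamma_mcp = 3,
                            gamma_scad = 3.7, tol = 1e-5, max_iter = 1000,
                            r2_min = 0.005,
                            families = names(PENALTY_FAMILIES)) {
  stopifnot(tol > 0, n_lambda >= 1, length(theta_grid) >= 1,
            all(families %in% names(PENALTY_FAMILIES)))
  structure(list(n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 theta_grid = theta_grid, alpha_grid = alpha_grid,
                 gamma_mcp = gamma_mcp, gamma_scad = gamma_scad, tol = tol,
                 max_iter = max_iter, r2_min = r2_min, families = families),
            class = "training_config")
}

#' Standardized marginal effect sizes from eQTL z-scores
#'
#' Approximates the SNP-expression correlation as
#' `r_j = Z_j / sqrt(N_j - 1 + Z_j^2)`, using each SNP's own sample size.
#' The formula bounds `|r_j| < 1` for finite z.
#'
#' @param table An [eqtl_summary()] (or a list with elements `z`, `n`).
#' @return Numeric vector of marginal correlations.
#' @export
standardized_marginal_effects <- function(table) {
  z <- table$z; n <- table$n
  if (any(!is.finite(z))) stop("non-finite eQTL z-score(s)")
  z / sqrt(n - 1 + z^2)
}

penalty_value <- function(w, penalty) {
  lam <- penalty$lambda; g <- penalty$gamma; a <- penalty$alpha
  aw <- abs(w)
  mcp_val <- function(aw, lam, g)
    ifelse(aw <= g * lam, lam * aw - aw^2 / (2 * g), g * lam^2 / 2)
  switch(penalty$family,
    lasso = lam * sum(aw),
    elastic_net = lam * sum(a * aw + (1 - a) * w^2 / 2),
    mcp = sum(mcp_val(aw, lam, g)),
    scad = sum(ifelse(aw <= lam, lam * aw,
                 ifelse(aw <= g * lam,
                        (2 * g * lam * aw - w^2 - lam^2) / (2 * (g - 1)),
                        lam^2 * (g + 1) / 2))),
    mnet = sum(mcp_val(aw, a * lam, g)) + (1 - a) * lam * sum(w^2) / 2)
}

#' Summary-statistics training objective
#'
#' Evaluates `w'Rw - 2 w'r + theta w'w + 2 J_lambda(w)`. The penalty enters
#' with a factor 2 so that the coordinate-descent updates are its exact
#' minimizers (see the package vignette); for the LASSO,
#' `J_lambda(w) = lambda * sum(|w|)`.
#'
#' @param w Weight vector.
#' @param r_tilde Standardized marginal effects
#'   ([standardized_marginal_effects()]).
#' @param R_tilde [ld_matrix()] or plain matrix, aligned with `w`.
#' @param penalty A [penalty_spec()].
#' @return Scalar objective value.
#' @export
sq_objective <- function(w, r_tilde, R_tilde, penalty) {
  R <- if (inherits(R_tilde, "ld_matrix")) R_tilde$values else R_tilde
  drop(t(w) %*% R %*% w) - 2 * sum(w * r_tilde) +
    penalty$theta * sum(w^2) + 2 * penalty_value(w, penalty)
}

#' Coordinate descent for the summary-statistics objective
#'
#' Cyclic coordinate descent from `w = 0` (or `w0`), sweeping until the
#' maximum absolute coordinate change falls below `tol`. Each update is the
#' exact univariate minimizer for the requested penalty family; under the
#' LASSO it is the soft threshold of the partial residual
#' `z_j = r_j - sum_{l != j} R_jl w_l` at `lambda`, divided by
#' `(1 + theta)`.
#'
#' @inheritParams sq_objective
#' @param tol,max_iter Convergence controls.
#' @param w0 Optional warm start.
#' @return List with `w`, logical `converged` and `iterations`. A
#'   non-converged fit warns rather than errors.
#' @export
coordinate_descent <- function(r_tilde, R_tilde, penalty, tol = 1e-5,
                               max_iter = 1000, w0 = NULL) {
  R <- if (inherits(R_tilde, "ld_matrix")) R_tilde$values else R_tilde
  p <- length(r_tilde)
  stopifnot(nrow(R) == p)
  if (is.null(w0)) w0 <- numeric(p)
  fit <- .cd_solve_cpp(R, r_tilde, PENALTY_FAMILIES[[penalty$family]],
                       penalty$lambda, penalty$gamma, penalty$alpha,
                       penalty$theta, tol, max_iter, w0)
  if (!fit$converged)
    warning("coordinate descent did not converge within ", max_iter,
            " sweeps")
  fit
}

#' Log-spaced penalty path
#'
#' `lambda_max` is the smallest penalty at which the LASSO solution is
#' identically zero, `max |r_j|` (divided by `alpha` for mixed penalties);
#' the grid descends log-linearly to `lambda_max * lambda_min_ratio`.
#'
#' @param r_tilde Marginal effects vector.
#' @param n_lambda Grid size.
#' @param lambda_min_ratio Ratio of smallest to largest lambda.
#' @param alpha L1 mixing fraction (1 for pure L1 penalties).
#' @return Decreasing numeric vector of lambda values; `0` if all `r_tilde`
#'   are zero.
#' @export
lambda_path <- function(r_tilde, n_lambda = 50, lambda_min_ratio = 0.01,
                        alpha = 1) {
  if (!length(r_tilde)) stop("empty marginal-effects vector")
  lmax <- max(abs(r_tilde)) / alpha
  if (lmax == 0) return(0)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

#' Squared correlation with a zero-variance guard
#'
#' @param pred,obs Numeric vectors.
#' @return `cor(pred, obs)^2`, or 0 when either vector has zero variance.
#' @export
r_squared <- function(pred, obs) {
  if (sd(pred) == 0 || sd(obs) == 0) return(0)
  cor(pred, obs)^2
}

#' Fitted per-gene weight model
#'
#' @param gene_id Gene identifier.
#' @param snps SNP metadata data frame aligned with `w_hat`.
#' @param w_hat Weight vector.
#' @param penalty The selected [penalty_spec()].
#' @param r2_tuning Tuning-set squared correlation.
#' @param r2_testing Validation-set squared correlation (`NA` until
#'   [validate_models()]).
#' @param converged Logical from the solver.
#' @return An object of class `weight_model`.
#' @export
weight_model <- function(gene_id, snps, w_hat, penalty, r2_tuning,
                         r2_testing = NA_real_, converged = TRUE) {
  stopifnot(length(w_hat) == nrow(snps))
  structure(list(gene_id = gene_id, snps = snps, w_hat = as.numeric(w_hat),
                 penalty = penalty, r2_tuning = r2_tuning,
                 r2_testing = r2_testing,
                 n_nonzero = sum(w_hat != 0), converged = converged),
            class = "weight_model")
}

#' @export
print.weight_model <- function(x, ...) {
  cat(sprintf("weight_model %s [%s]: %d/%d nonzero, tuning R2 = %.4g%s\n",
              x$gene_id, x$penalty$family, x$n_nonzero, length(x$w_hat),
              x$r2_tuning,
              if (is.na(x$r2_testing)) ""
              else sprintf(", testing R2 = %.4g", x$r2_testing)))
  invisible(x)
}

# Align a (genotypes, expression) panel to the SNP order of a model/table.
align_panel_matrix <- function(genotypes, snp_ids) {
  g <- if (inherits(genotypes, "reference_panel")) genotypes$genotypes
       else as.matrix(genotypes)
  if (!is.null(colnames(g))) {
    idx <- match(snp_ids, colnames(g))
    if (anyNA(idx)) stop("tuning/testing genotypes lack SNP(s): ",
                         paste(snp_ids[is.na(idx)][1:3], collapse = ", "))
    g <- g[, idx, drop = FALSE]
  } else if (ncol(g) != length(snp_ids)) {
    stop("unnamed genotype matrix must match the SNP count")
  }
  g
}

#' Fit the per-penalty-family expression models for one gene
#'
#' For each penalty family, fits the full (lambda, theta[, alpha]) grid by
#' warm-started coordinate descent on the summary statistics, scores every
#' grid point by the squared correlation between predicted and observed
#' expression on the tuning panel, and keeps the best point. Ties are
#' broken toward the sparser model, then the larger lambda; an all-zero fit
#' scores R-squared 0.
#'
#' @param table [eqtl_summary()] for the gene (harmonized to the panel).
#' @param R_tilde [ld_matrix()] over the same SNPs (normally shrunk).
#' @param tuning List with `genotypes` (samples x SNPs; columns matched by
#'   name when present) and `expression` (covariate-residualized,
#'   standardized).
#' @param config A [training_config()].
#' @return Named list of [weight_model()] objects, one per family.
#' @export
fit_gene <- function(table, R_tilde, tuning, config = training_config()) {
  if (length(tuning$expression) < 10)
    stop("tuning panel must have at least 10 samples")
  r_tilde <- standardized_marginal_effects(table)
  fit_gene_marginal(table$gene_id, table$snps, r_tilde, R_tilde, tuning,
                    config)
}

# Grid fit from precomputed marginal effects (shared with the simulation
# oracle arm, which supplies exact in-sample correlations).
fit_gene_marginal <- function(gene_id, snps, r_tilde, R_tilde, tuning,
                              config) {
  R <- if (inherits(R_tilde, "ld_matrix")) R_tilde$values else R_tilde
  x_tune <- standardize_genotypes(align_panel_matrix(tuning$genotypes,
                                                     snps$snp_id))
  e_tune <- tuning$expression
  out <- list()
  for (fam in config$families) {
    alphas <- if (fam %in% c("elastic_net", "mnet")) config$alpha_grid else 1
    gamma <- if (fam == "scad") config$gamma_scad else config$gamma_mcp
    W <- NULL; meta <- NULL
    for (a in alphas) {
      lams <- lambda_path(r_tilde, config$n_lambda, config$lambda_min_ratio,
                          alpha = a)
      for (th in config$theta_grid) {
        path <- .cd_path_cpp(R, r_tilde, PENALTY_FAMILIES[[fam]], lams,
                             gamma, a, th, config$tol, config$max_iter)
        W <- cbind(W, path$W)
        meta <- rbind(meta, data.frame(lambda = lams, theta = th, alpha = a,
                                       converged = as.logical(path$converged)))
      }
    }
    pred <- x_tune %*% W
    r2 <- apply(pred, 2, r_squared, obs = e_tune)
    nnz <- colSums(W != 0)
    r2[nnz == 0] <- 0
    # best R2; ties -> sparsest, then largest lambda
    best <- order(-r2, nnz, -meta$lambda)[1]
    spec <- penalty_spec(fam, lambda = meta$lambda[best],
                         gamma = gamma, alpha = meta$alpha[best],
                         theta = meta$theta[best])
    out[[fam]] <- weight_model(gene_id, snps, W[, best], spec,
                               r2_tuning = r2[best],
                               converged = meta$converged[best])
  }
  out
}

#' Validate weight models on held-out expression and apply the admission
#' rule
#'
#' Fills `r2_testing` (squared correlation between predicted and observed
#' expression on the validation panel, disjoint from tuning) and keeps only
#' models with `r2_testing >= r2_min`. The boundary value is admitted.
#'
#' @param models List of [weight_model()] objects.
#' @param testing List with `genotypes` and `expression`, as in
#'   [fit_gene()].
#' @param r2_min Admission threshold (default 0.005).
#' @return The admitted models, with `r2_testing` filled in.
#' @export
validate_models <- function(models, testing, r2_min = 0.005) {
  if (!length(models)) return(models)
  scored <- lapply(models, function(m) {
    x <- standardize_genotypes(align_panel_matrix(testing$genotypes,
                                                  m$snps$snp_id))
    m$r2_testing <- r_squared(drop(x %*% m$w_hat), testing$expression)
    m
  })
  keep <- vapply(scored, function(m) m$r2_testing >= r2_min, logical(1))
  scored[keep]
}

#' Null calibration of the prediction R-squared admission threshold
#'
#' Under a standard multiple regression with no true signal, the in-sample
#' R-squared of a model with `p_nonzero` regressors on `n` observations
#' follows Beta((p-1)/2, (n-p)/2) (Cramer). The returned (1 - alpha)
#' quantile is the lower edge of the null rejection region for R-squared.
#'
#' @param p_nonzero Number of regressors (`>= 2`).
#' @param n Sample size (`> p_nonzero`).
#' @param alpha Significance level in (0, 1).
#' @return Scalar threshold.
#' @export
cramer_r2_threshold <- function(p_nonzero, n, alpha) {
  if (p_nonzero < 2 || n <= p_nonzero) stop("need n > p >= 2")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  qbeta(1 - alpha, (p_nonzero - 1) / 2, (n - p_nonzero) / 2)
}

#' Write / read a weight-model database
#'
#' Two tab-delimited files: per-SNP nonzero weights
#' (`gene_id, snp_id, ref, alt, penalty_family, weight`) and per-model
#' metadata (`gene_id, family, lambda, theta, gamma, alpha, r2_tuning,
#' r2_testing, n_nonzero`).
#'
#' @param models List of [weight_model()] objects.
#' @param weights_path,meta_path Output paths.
#' @return `write_weight_models()`: the paths, invisibly.
#'   `read_weight_models()`: a list of [weight_model()] objects restricted
#'   to their nonzero SNPs.
#' @export
write_weight_models <- function(models, weights_path, meta_path) {
  wt <- do.call(rbind, lapply(models, function(m) {
    nz <- which(m$w_hat != 0)
    if (!length(nz)) return(NULL)
    data.frame(gene_id = m$gene_id, snp_id = m$snps$snp_id[nz],
               ref = m$snps$ref[nz], alt = m$snps$alt[nz],
               penalty_family = m$penalty$family, weight = m$w_hat[nz],
               stringsAsFactors = FALSE)
  }))
  if (is.null(wt)) wt <- data.frame(gene_id = character(), snp_id = character(),
                                    ref = character(), alt = character(),
                                    penalty_family = character(),
                                    weight = numeric())
  meta <- do.call(rbind, lapply(models, function(m)
    data.frame(gene_id = m$gene_id, family = m$penalty$family,
               lambda = m$penalty$lambda, theta = m$penalty$theta,
               gamma = m$penalty$gamma, alpha = m$penalty$alpha,
               r2_tuning = m$r2_tuning, r2_testing = m$r2_testing,
               n_nonzero = m$n_nonzero, stringsAsFactors = FALSE)))
  write.table(wt, weights_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(weights_path, meta_path))
}

#' @rdname write_weight_models
#' @export
read_weight_models <- function(weights_path, meta_path) {
  wt <- read.delim(weights_path, stringsAsFactors = FALSE)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(meta)), function(i) {
    mi <- meta[i, ]
    rows <- wt[wt$gene_id == mi$gene_id & wt$penalty_family == mi$family, ,
               drop = FALSE]
    snps <- data.frame(snp_id = rows$snp_id, chrom = NA_character_,
                       pos = 1, ref = rows$ref, alt = rows$alt,
                       stringsAsFactors = FALSE)
    weight_model(mi$gene_id, snps, rows$weight,
                 penalty_spec(mi$family, lambda = mi$lambda, gamma = mi$gamma,
                              alpha = mi$alpha, theta = mi$theta),
                 r2_tuning = mi$r2_tuning, r2_testing = mi$r2_testing)
  })
  out
}
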