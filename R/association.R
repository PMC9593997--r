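# Gene-trait association from GWAS summary statistics: burden-type test per
# weight model, R-squared-weighted Cauchy combination across models, and
# majority-vote direction calls.

#' Burden-type gene-trait test from GWAS z-scores
#'
#' Computes `z_tilde = sum(Z * w) / sqrt(w' V w)` where `Z` are the GWAS
#' z-scores over the model's SNPs and `V` their LD matrix (normally the
#' shrinkage estimator from a reference panel), with a two-sided normal
#' p-value. The statistic is invariant to positive rescaling of `w` and
#' flips sign when `w` does.
#'
#' @param w_hat Weight vector with at least one nonzero entry.
#' @param gwas A [gwas_summary()] or plain z-score vector aligned with
#'   `w_hat`.
#' @param V [ld_matrix()] or matrix aligned with `w_hat`'s SNP order.
#' @return List with `z_tilde` and `p_value`.
#' @export
burden_test <- function(w_hat, gwas, V) {
  z <- if (inherits(gwas, "gwas_summary")) gwas$z else as.numeric(gwas)
  Vm <- if (inherits(V, "ld_matrix")) V$values else as.matrix(V)
  if (all(w_hat == 0)) stop("all-zero weight vector; nothing to test")
  if (length(z) != length(w_hat) || nrow(Vm) != length(w_hat))
    stop("w_hat, z and V must be aligned")
  q <- drop(t(w_hat) %*% Vm %*% w_hat)
  if (q <= 0)
    stop("w'Vw <= 0 (indefinite LD estimate); use the shrunk or ridged V")
  zt <- sum(z * w_hat) / sqrt(q)
  list(z_tilde = zt, p_value = 2 * pnorm(-abs(zt)))
}

#' Gene-trait test from individual-level GWAS data
#'
#' Regresses the phenotype on the predicted expression
#' `genotypes %*% w_hat` (plus covariates) under an identity (linear) or
#' logit link, returning the Wald test of the expression coefficient.
#'
#' @param w_hat Weight vector.
#' @param genotypes Samples x SNPs matrix aligned with `w_hat` (columns
#'   matched by name when present); standardized internally.
#' @param phenotype Numeric (identity link) or 0/1 (logit link) vector.
#' @param covariates Optional numeric matrix of covariates.
#' @param link `"identity"` or `"logit"`.
#' @return List with `beta`, `se`, `z` and `p_value`.
#' @export
glm_association <- function(w_hat, genotypes, phenotype, covariates = NULL,
                            link = c("identity", "logit")) {
  link <- match.arg(link)
  g <- if (inherits(genotypes, "reference_panel")) genotypes$genotypes
       else as.matrix(genotypes)
  x <- standardize_genotypes(g)
  expr <- drop(x %*% w_hat)
  if (sd(expr) == 0) stop("predicted expression has zero variance")
  dat <- data.frame(y = phenotype, expr = expr)
  form <- y ~ expr
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (qr(cbind(1, covariates))$rank < ncol(covariates) + 1)
      stop("collinear covariates")
    dat <- cbind(dat, covariates)
    form <- stats::reformulate(c("expr", colnames(as.data.frame(covariates))),
                               response = "y")
  }
  fit <- if (link == "identity") lm(form, data = dat)
         else glm(form, data = dat, family = binomial())
  sm <- summary(fit)$coefficients["expr", ]
  z <- sm[1] / sm[2]
  list(beta = unname(sm[1]), se = unname(sm[2]), z = unname(z),
       p_value = unname(2 * pnorm(-abs(z))))
}

#' Cauchy combination of dependent p-values
#'
#' Combines model p-values as `T = sum w_j * tan((0.5 - p_j) * pi)` with
#' weights normalized to sum 1 (here the models' prediction R-squared
#' values); under the null T is approximately standard Cauchy and the
#' combined p-value is `0.5 - arctan(T) / pi`. For `p_j < 1e-15` the
#' tail-equivalent term `w_j / (p_j * pi)` avoids overflow, and very large
#' T maps back through the matching tail `1 / (pi * T)`.
#'
#' @param p_values Vector of p-values, each strictly inside (0, 1).
#' @param r2_weights Non-negative weights, not all zero (defaults to equal).
#' @return Combined p-value.
#' @export
cauchy_combine <- function(p_values, r2_weights = rep(1, length(p_values))) {
  if (!length(p_values)) stop("no p-values to combine")
  if (any(!is.finite(p_values) | p_values <= 0 | p_values >= 1))
    stop("p-values must lie strictly inside (0, 1)")
  if (any(r2_weights < 0) || sum(r2_weights) == 0)
    stop("weights must be non-negative and not all zero")
  w <- r2_weights / sum(r2_weights)
  small <- p_values < 1e-15
  terms <- numeric(length(p_values))
  terms[small] <- w[small] / (p_values[small] * pi)
  terms[!small] <- w[!small] * tan((0.5 - p_values[!small]) * pi)
  T_stat <- sum(terms)
  if (T_stat > 1e15) 1 / (pi * T_stat) else 0.5 - atan(T_stat) / pi
}

#' Majority-vote association direction
#'
#' @param signs Vector of per-model direction signs: `+1`/`-1` or
#'   `"+"`/`"-"`.
#' @return `"+"`, `"-"`, or `"unknown"` on an exact tie.
#' @export
direction_vote <- function(signs) {
  if (!length(signs)) stop("no models to vote on")
  if (is.character(signs)) signs <- ifelse(signs == "+", 1, -1)
  s <- sum(sign(signs))
  if (s > 0) "+" else if (s < 0) "-" else "unknown"
}

#' Transcriptome-wide association scan
#'
#' Runs the burden test for every admitted weight model, combines per-gene
#' p-values with the validation-R-squared-weighted Cauchy combination,
#' calls direction by majority vote, and flags Bonferroni significance at
#' `alpha / n_tested`, where `n_tested` counts genes with at least one
#' model and at least one GWAS-overlapping SNP. Genes with zero overlapping
#' SNPs are reported as untested rows, not errors.
#'
#' @param models List of [weight_model()] objects (possibly several per
#'   gene).
#' @param gwas A [gwas_summary()] harmonized to the reference panel.
#' @param panel A [reference_panel()] for the LD of the tested SNPs.
#' @param map Optional genetic map (data frame `pos`, `cm`); when supplied
#'   (or when the panel carries `cm`) and `shrink = TRUE`, the shrinkage LD
#'   estimator is used for V.
#' @param alpha Family-wise significance level (default 0.05).
#' @param shrink Use the shrinkage LD estimator for V (default TRUE; falls
#'   back to raw sample LD when no genetic positions are available).
#' @return Data frame with one row per gene, sorted by combined p-value:
#'   `gene_id, n_models, n_snps, z_per_model, p_per_model, combined_p,
#'   direction, tested, significant`.
#' @export
transcriptome_scan <- function(models, gwas, panel, map = NULL, alpha = 0.05,
                               shrink = TRUE) {
  genes <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  rows <- lapply(names(genes), function(gid) {
    mods <- genes[[gid]]
    res <- lapply(mods, function(m) {
      nz <- which(m$w_hat != 0)
      ids <- m$snps$snp_id[nz]
      common <- ids[ids %in% gwas$snps$snp_id & ids %in% panel$snps$snp_id]
      if (!length(common)) return(NULL)
      w <- m$w_hat[nz][match(common, ids)]
      z <- gwas$z[match(common, gwas$snps$snp_id)]
      sub <- subset_snp_table(panel, match(common, panel$snps$snp_id))
      V <- sample_ld(sub)
      if (shrink) {
        cm <- if (!is.null(map)) interpolate_cm(sub$snps, map)
              else if ("cm" %in% names(sub$snps)) sub$snps$cm else NULL
        if (!is.null(cm) && !anyNA(cm)) V <- shrink_ld(V, cm)
      }
      bt <- burden_test(w, z, V)
      list(z = bt$z_tilde, p = bt$p_value, r2 = m$r2_testing)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res))
      return(data.frame(gene_id = gid, n_models = 0L, n_snps = 0L,
                        z_per_model = "", p_per_model = "",
                        combined_p = NA_real_, direction = "unknown",
                        tested = FALSE, stringsAsFactors = FALSE))
    zs <- vapply(res, `[[`, numeric(1), "z")
    ps <- vapply(res, `[[`, numeric(1), "p")
    r2 <- vapply(res, `[[`, numeric(1), "r2")
    if (all(is.na(r2))) r2 <- rep(1, length(ps))
    ps_in <- pmin(pmax(ps, 1e-300), 1 - 1e-16) # guard exact 0/1 from pnorm
    data.frame(gene_id = gid, n_models = length(res),
               n_snps = sum(vapply(mods, function(m) m$n_nonzero, numeric(1))),
               z_per_model = paste(signif(zs, 6), collapse = ","),
               p_per_model = paste(signif(ps, 6), collapse = ","),
               combined_p = cauchy_combine(ps_in, r2),
               direction = direction_vote(sign(zs)),
               tested = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  n_tested <- sum(out$tested)
  out$significant <- out$tested & !is.na(out$combined_p) &
    out$combined_p < alpha / max(n_tested, 1)
  attr(out, "n_tested") <- n_tested
  attr(out, "threshold") <- alpha / max(n_tested, 1)
  out[order(out$combined_p), , drop = FALSE]
}
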