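# Configuration and orchestration: YAML run configs with validated keys and
# filled-in defaults, and a train -> assoc -> simulate pipeline that writes
# versioned outputs plus a checksum manifest.

default_run_config <- function() {
  list(
    seed = 1L,
    log_level = "info",
    paths = list(eqtl = NULL, gwas = NULL, panel = NULL, map = NULL,
                 annotation = NULL, tuning_panel = NULL,
                 testing_panel = NULL, tuning_expression = NULL,
                 testing_expression = NULL, weights = NULL, meta = NULL,
                 hapmap3 = NULL, out = "sumtwas_out"),
    filters = list(maf_min = 0.01, window_bp = 1e6),
    ld = list(N_e = 11400, m = 183, c = 1e-3, shrink = TRUE),
    training = list(n_lambda = 50, lambda_min_ratio = 0.01,
                    theta_grid = c(0, 0.1, 0.2, 0.4, 0.8), alpha_grid = 0.5,
                    gamma_mcp = 3, gamma_scad = 3.7, tol = 1e-5,
                    max_iter = 1000, r2_min = 0.005,
                    families = names(PENALTY_FAMILIES)),
    association = list(alpha = 0.05, shrink_v = TRUE),
    simulation = list(scenario = "accuracy", n_train = 31684, n_tune = 369,
                      n_test = 10000, p_snps = 877, h_e2 = 0.1, h_p2 = 0.2,
                      p_causal = 0.05, n_replicates = 100,
                      sig_threshold = 2.5e-6)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                         !is.null(names(defaults[[k]])))
      merge_config(defaults[[k]], user[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Validate and resolve a YAML run configuration
#'
#' Reads a YAML file, rejects unknown keys (naming them), fills every
#' missing value with its default (shrinkage N_e = 11,400, m = 183,
#' c = 1e-3; admission R-squared 0.005; cis window 1 Mb; MAF minimum 0.01),
#' verifies that all referenced input files exist (listing every missing
#' one at once), and echoes the resolved values. An empty file is a valid
#' all-defaults configuration.
#'
#' @param path Path to the YAML file.
#' @param quiet Suppress the resolved-value echo.
#' @return The resolved configuration, class `run_config`.
#' @export
validate_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_run_config(), user)
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed) || cfg$seed < 0)
    stop("seed must be a non-negative integer")
  file_keys <- setdiff(names(cfg$paths), c("out", "weights", "meta"))
  refs <- unlist(cfg$paths[file_keys])
  plink_keys <- c("panel", "tuning_panel", "testing_panel")
  check <- vapply(names(refs), function(k) {
    if (k %in% plink_keys) file.exists(paste0(refs[[k]], ".bed"))
    else file.exists(refs[[k]])
  }, logical(1))
  if (any(!check))
    stop("missing input file(s): ",
         paste(sprintf("%s=%s", names(refs)[!check], refs[!check]),
               collapse = ", "))
  if (!quiet)
    message("resolved config: seed=", cfg$seed,
            " N_e=", cfg$ld$N_e, " m=", cfg$ld$m, " c=", cfg$ld$c,
            " r2_min=", cfg$training$r2_min,
            " window_bp=", cfg$filters$window_bp,
            " maf_min=", cfg$filters$maf_min)
  structure(cfg, class = "run_config")
}

as_training_config <- function(cfg) {
  do.call(training_config, cfg$training)
}

read_expression_file <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(df) <- df[[1]]
  as.matrix(df[, -1, drop = FALSE])
}

pipeline_train <- function(cfg) {
  genes <- read_gene_annotation(cfg$paths$annotation)
  panel <- read_plink(cfg$paths$panel)
  tune_panel <- read_plink(cfg$paths$tuning_panel)
  test_panel <- read_plink(cfg$paths$testing_panel)
  tune_expr <- read_expression_file(cfg$paths$tuning_expression)
  test_expr <- read_expression_file(cfg$paths$testing_expression)
  map <- if (!is.null(cfg$paths$map)) read_genetic_map(cfg$paths$map)
  hapmap3 <- if (!is.null(cfg$paths$hapmap3))
    readLines(cfg$paths$hapmap3) else character()
  tc <- as_training_config(cfg)
  all_models <- list()
  for (gene in genes) {
    if (!(gene$gene_id %in% colnames(tune_expr))) next
    tab <- load_eqtl_summary(cfg$paths$eqtl, gene)
    if (nrow(tab$snps) == 0) next
    tab <- restrict_to_cis_window(tab, gene, cfg$filters$window_bp)
    tab <- filter_snps(tab, panel, hapmap3, cfg$filters$maf_min)
    tab <- harmonize_alleles(tab, panel)
    if (nrow(tab$snps) == 0) next
    sub <- subset_snp_table(panel,
                            match(tab$snps$snp_id, panel$snps$snp_id))
    ld <- sample_ld(sub)
    if (cfg$ld$shrink) {
      cm <- if (!is.null(map)) interpolate_cm(sub$snps, map)
            else sub$snps$cm
      ld <- shrink_ld(ld, cm, cfg$ld$N_e, cfg$ld$m, cfg$ld$c)
    }
    fits <- fit_gene(tab, ld,
                     list(genotypes = tune_panel,
                          expression = tune_expr[, gene$gene_id]), tc)
    fits <- validate_models(fits,
                            list(genotypes = test_panel,
                                 expression = test_expr[, gene$gene_id]),
                            tc$r2_min)
    all_models <- c(all_models, fits)
  }
  wt <- file.path(cfg$paths$out, "weights.tsv")
  mt <- file.path(cfg$paths$out, "weights_meta.tsv")
  write_weight_models(all_models, wt, mt)
  c(weights = wt, meta = mt)
}

pipeline_assoc <- function(cfg) {
  wt <- cfg$paths$weights
  mt <- cfg$paths$meta
  if (is.null(wt)) wt <- file.path(cfg$paths$out, "weights.tsv")
  if (is.null(mt)) mt <- file.path(cfg$paths$out, "weights_meta.tsv")
  if (!file.exists(wt) || !file.exists(mt))
    stop("assoc stage needs a weight database; run the train stage first ",
         "or set paths$weights / paths$meta")
  models <- read_weight_models(wt, mt)
  if (!length(models)) stop("weight database is empty")
  panel <- read_plink(cfg$paths$panel)
  gwas <- load_gwas_summary(cfg$paths$gwas)
  gwas <- harmonize_alleles(gwas, panel)
  map <- if (!is.null(cfg$paths$map)) read_genetic_map(cfg$paths$map)
  scan <- transcriptome_scan(models, gwas, panel, map,
                             alpha = cfg$association$alpha,
                             shrink = cfg$association$shrink_v)
  out <- file.path(cfg$paths$out, "associations.tsv")
  write.table(scan, out, sep = "\t", quote = FALSE, row.names = FALSE)
  c(associations = out)
}

pipeline_simulate <- function(cfg) {
  sc <- cfg$simulation
  conf <- sim_config(n_train = sc$n_train, n_tune = sc$n_tune,
                     n_test = sc$n_test, p_snps = sc$p_snps, h_e2 = sc$h_e2,
                     h_p2 = sc$h_p2, p_causal = sc$p_causal,
                     n_replicates = sc$n_replicates, seed = cfg$seed,
                     sig_threshold = sc$sig_threshold,
                     training = as_training_config(cfg))
  res <- switch(sc$scenario,
                accuracy = run_accuracy_experiment(conf),
                power = run_power_experiment(conf),
                type1 = run_type1_experiment(conf),
                stop("unknown simulation scenario: ", sc$scenario))
  out_tsv <- file.path(cfg$paths$out,
                       paste0("simulation_", sc$scenario, ".tsv"))
  summ <- res[setdiff(names(res), c("results", "p_values", "config"))]
  if (!is.null(res$results))
    write.table(res$results, out_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  else write.table(data.frame(p_value = res$p_values), out_tsv, sep = "\t",
                   quote = FALSE, row.names = FALSE)
  out_json <- file.path(cfg$paths$out,
                        paste0("simulation_", sc$scenario, ".json"))
  jsonlite::write_json(summ, out_json, auto_unbox = TRUE, digits = NA)
  c(simulation_tsv = out_tsv, simulation_json = out_json)
}

#' Run the analysis pipeline
#'
#' Orchestrates the requested stages (`train`: build the per-gene weight
#' database; `assoc`: transcriptome-wide association scan; `simulate`: one
#' of the simulation experiments) and writes a manifest with input/output
#' checksums and the resolved configuration. Reruns with identical inputs
#' and seed reproduce identical output tables.
#'
#' @param config A `run_config` from [validate_config()] (or a path to a
#'   YAML file).
#' @param stages Character subset of `c("train", "assoc", "simulate")`.
#' @return Named character vector of output paths, invisibly.
#' @export
run_pipeline <- function(config, stages = c("train", "assoc")) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(all(stages %in% c("train", "assoc", "simulate")))
  dir.create(config$paths$out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  outputs <- character()
  for (st in stages) {
    outputs <- c(outputs, switch(st,
                                 train = pipeline_train(config),
                                 assoc = pipeline_assoc(config),
                                 simulate = pipeline_simulate(config)))
  }
  inputs <- unlist(config$paths[
    !vapply(config$paths, is.null, logical(1))])
  inputs <- inputs[file.exists(inputs) & !dir.exists(inputs)]
  manifest <- list(
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config = unclass(config),
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(outputs[file.exists(outputs)])))
  jsonlite::write_json(manifest, file.path(config$paths$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outputs)
}
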