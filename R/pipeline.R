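# Configuration, logging and the end-to-end driver:
# simulate -> qc -> prep -> fit -> gwas -> coloc -> report.

.config_defaults <- function() {
  list(
    seed = 1L,
    out_dir = "semscan_run",
    simulate = list(n_samples = 1966L, n_variants = 2000L,
                    maf_range = c(0.05, 0.5), ld_block_size = 20L,
                    ld_rho = 0.8, causal_index = NA, causal_beta = NA,
                    eqtl_scenarios = c("shared", "distinct", "null"),
                    eqtl_n = 500L, eqtl_effect = 0.8),
    qc = list(min_call_rate = 0.95, min_maf = 0.01, max_ibd = 0.1875,
              min_hwe_p = 1e-6),
    scan = list(suggestive = 1e-5, genome_wide = 5e-8, r2_threshold = 0.6,
                window_kb = 500, flank_kb = 100, n_components = 2L),
    coloc = list(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5, prior_sd = 0.15,
                 report_threshold = 0.5, strong_threshold = 0.75)
  )
}

#' Load and validate a pipeline configuration
#'
#' YAML file with the sections `simulate`, `qc`, `scan`, `coloc` (all
#' optional; defaults fill in the thresholds: suggestive 1e-5, genome-wide
#' 5e-8, r-squared 0.6, flank 100 kb, coloc priors 1e-4/1e-4/1e-5).  Unknown
#' keys are rejected.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return a validated `pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  defaults <- .config_defaults()
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0)
    stop_semscan(paste("unknown config keys:", paste(bad, collapse = ", ")),
                 "semscan_validation_error")
  for (sec in intersect(names(user), c("simulate", "qc", "scan", "coloc"))) {
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0)
      stop_semscan(sprintf("unknown config key in '%s': %s", sec,
                           paste(bad, collapse = ", ")),
                   "semscan_validation_error")
  }
  cfg <- modifyList(defaults, user)
  with(cfg, {
    if (qc$min_maf < 0 || qc$min_maf > 1)
      stop_semscan("qc.min_maf must lie in [0, 1]", "semscan_validation_error")
    if (scan$suggestive <= 0 || scan$genome_wide <= 0 ||
        scan$r2_threshold <= 0 || scan$flank_kb <= 0)
      stop_semscan("scan thresholds must be positive",
                   "semscan_validation_error")
    if (coloc$p1 <= 0 || coloc$p2 <= 0 || coloc$p12 <= 0)
      stop_semscan("coloc priors must be positive", "semscan_validation_error")
  })
  structure(cfg, class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

.log_stage <- function(log_path, stage, ...) {
  msg <- sprintf("[%s] %s", stage, paste(sprintf(...), collapse = ""))
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes simulate, QC, questionnaire preprocessing, measurement-model fit,
#' multi-trait scan with genomic control, locus definition and colocalization
#' against the simulated eQTL panels; writes all intermediate tables plus a
#' machine-readable manifest (`manifest.json`: seed, lambda_GC, loci count,
#' coloc hits) under `config$out_dir`.
#'
#' @param config a `pipeline_config` from [load_config()].
#' @return the manifest list, invisibly; side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = load_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  cat("", file = log_path)
  stage <- "simulate"
  ver <- tryCatch(as.character(utils::packageVersion("semscan")),
                  error = function(e) "dev")
  manifest <- list(package_version = ver, seed = config$seed)
  result <- tryCatch({
    sc <- config$simulate
    causal <- if (!is.na(sc$causal_index) && !is.na(sc$causal_beta))
      data.frame(index = sc$causal_index, beta = sc$causal_beta) else NULL
    simcfg <- sim_config(n_samples = sc$n_samples, n_variants = sc$n_variants,
                         maf_range = sc$maf_range,
                         ld_block_size = sc$ld_block_size, ld_rho = sc$ld_rho,
                         causal_variants = causal, seed = config$seed)
    geno <- simulate_genotypes(simcfg)
    phen <- simulate_phenotypes(geno, simcfg)
    export_dataset(geno, phen, file.path(config$out_dir, "data"))
    .log_stage(log_path, stage, "n=%d samples, m=%d variants, seed=%d",
               sc$n_samples, sc$n_variants, config$seed)

    stage <- "qc"
    qc <- variant_qc(geno, qc_thresholds(config$qc$min_call_rate,
                                         config$qc$min_maf, config$qc$max_ibd,
                                         config$qc$min_hwe_p))
    geno <- qc$genotypes
    write.table(data.frame(filter = names(qc$report$removed),
                           removed = qc$report$removed),
                file.path(config$out_dir, "qc_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .log_stage(log_path, stage, "%d -> %d variants", qc$report$variants_in,
               qc$report$variants_out)
    manifest$variants_post_qc <- qc$report$variants_out

    stage <- "prep"
    deltas <- delta_scores(phen$questionnaire)
    cats <- category_scores(deltas)
    write.table(cats, file.path(config$out_dir, "category_scores.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    net <- covariance_selection(cor(as.matrix(deltas[, -1])), nrow(deltas))
    write.table(net$pcor, file.path(config$out_dir, "partial_correlations.tsv"),
                sep = "\t", quote = FALSE)
    .log_stage(log_path, stage, "%d network edges kept",
               sum(net$adjacency[upper.tri(net$adjacency)] != 0))

    stage <- "fit"
    covars <- phen$covariates[, c("age", "sex")]
    fit0 <- fit_one_factor(cats[, -1], covariates = covars)
    .log_stage(log_path, stage, "chi2=%.2f df=%d rmsea=%.3f", fit0$chi_square,
               fit0$df, fit0$rmsea["estimate"])
    manifest$measurement_fit <- list(chi_square = fit0$chi_square,
                                     df = fit0$df,
                                     rmsea = unname(fit0$rmsea["estimate"]),
                                     loadings = as.list(fit0$loadings))

    stage <- "gwas"
    tab <- run_scan(geno, cats[, -1], covars)
    write.table(as.data.frame(tab),
                file.path(config$out_dir, "summary_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    export_plots_data(tab, file.path(config$out_dir, "plots"))
    loci <- define_loci(tab, geno, p_threshold = config$scan$suggestive,
                        r2_threshold = config$scan$r2_threshold,
                        window_kb = config$scan$window_kb)
    write.table(loci[, setdiff(names(loci), "members")],
                file.path(config$out_dir, "loci.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .log_stage(log_path, stage, "lambda_GC=%.3f, %d loci",
               attr(tab, "lambda_gc"), nrow(loci))
    manifest$lambda_gc <- attr(tab, "lambda_gc")
    manifest$n_loci <- nrow(loci)

    stage <- "coloc"
    coloc_tab <- NULL
    if (nrow(loci) > 0) {
      panels <- lapply(setNames(sc$eqtl_scenarios, sc$eqtl_scenarios),
                       function(scn) simulate_eqtl_summary(
                         geno, scn, simcfg, n_eqtl = sc$eqtl_n,
                         effect = sc$eqtl_effect,
                         gene = paste0("GENE_", scn), tissue = "simulated"))
      coloc_tab <- coloc_batch(tab, loci, panels,
                               flank_kb = config$scan$flank_kb,
                               report_threshold = config$coloc$report_threshold,
                               strong_threshold = config$coloc$strong_threshold,
                               p1 = config$coloc$p1, p2 = config$coloc$p2,
                               p12 = config$coloc$p12,
                               prior_sd = config$coloc$prior_sd)
      write.table(coloc_tab, file.path(config$out_dir, "coloc_results.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    n_hits <- if (is.null(coloc_tab)) 0L else sum(coloc_tab$reported)
    .log_stage(log_path, stage, "%d coloc tests, %d reported hits",
               if (is.null(coloc_tab)) 0L else nrow(coloc_tab), n_hits)
    manifest$coloc_hits <- n_hits
    manifest$coloc_max_pph4 <- if (!is.null(coloc_tab) && nrow(coloc_tab) > 0)
      max(coloc_tab$pph4) else NA
    manifest
  }, error = function(e) {
    .log_stage(log_path, stage, "FAILED: %s", conditionMessage(e))
    stop_semscan(sprintf("pipeline stage '%s' failed: %s (artifacts under %s)",
                         stage, conditionMessage(e), config$out_dir),
                 "semscan_pipeline_error")
  })
  jsonlite::write_json(result, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
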