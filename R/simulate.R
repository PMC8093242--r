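# Synthetic cohort generator: HWE genotypes with block LD, age/sex covariates,
# one-factor Likert questionnaire responses, and paired eQTL summary statistics.
# Ground truth is returned alongside so recovery tests never reach into internals.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator.  Defaults emulate the
#' statistical structure of a questionnaire-based eye-strain study: 1966
#' post-QC subjects, a one-common-factor measurement model over four symptom
#' categories with loadings (0.842, 0.657, 0.787, 0.823), age/sex covariate
#' effects on the latent trait, and block-wise LD genotypes in Hardy-Weinberg
#' equilibrium.
#'
#' @param n_samples number of subjects.
#' @param n_variants number of autosomal variants.
#' @param maf_range length-2 numeric in (0, 1): minor allele frequencies are
#'   drawn uniformly from this interval.
#' @param ld_block_size variants per LD block.
#' @param ld_rho within-block adjacent-haplotype correlation in `[0, 1)`;
#'   correlation decays as `ld_rho^distance` (first-order autoregression).
#' @param causal_variants data frame with columns `index` (variant index) and
#'   `beta` (effect of one allele-dose on the latent factor), or `NULL`.
#' @param loadings four factor loadings in (0, 1), one per symptom category
#'   (asthenopic, ocular-surface, visual, extra-ocular).
#' @param covariate_effects named numeric: effects of standardized `age` and
#'   `sex` on the latent factor.
#' @param likert_thresholds six strictly increasing cut points mapping a
#'   continuous propensity to the 1–7 response scale.
#' @param likert_shift shift of the response propensity between the low-load
#'   and high-load conditions, in propensity units; with the default equally
#'   spaced thresholds it sets the mean delta score.
#' @param likert_scale slope of the high-load propensity on the continuous
#'   item score.
#' @param item_noise_sd standard deviation of item-specific noise around the
#'   category score.
#' @param seed integer seed; identical configs give byte-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 1966L,
                       n_variants = 2000L,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 20L,
                       ld_rho = 0.8,
                       causal_variants = NULL,
                       loadings = c(0.842, 0.657, 0.787, 0.823),
                       covariate_effects = c(age = 0.1, sex = 0.1),
                       likert_thresholds = seq(-0.25, 3.5, by = 0.75),
                       likert_shift = 2.0,
                       likert_scale = 1.3,
                       item_noise_sd = 0.25,
                       seed = 1L) {
  if (!is_count(n_samples) || n_samples < 2)
    stop_semscan("n_samples must be an integer >= 2", "semscan_config_error")
  if (!is_count(n_variants) || n_variants < 1)
    stop_semscan("n_variants must be a positive integer", "semscan_config_error")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2])
    stop_semscan("maf_range must be an ordered pair within (0, 1)",
                 "semscan_config_error")
  if (!is.numeric(ld_rho) || ld_rho < 0 || ld_rho >= 1)
    stop_semscan("ld_rho must lie in [0, 1)", "semscan_config_error")
  if (!is_count(ld_block_size) || ld_block_size < 1)
    stop_semscan("ld_block_size must be a positive integer", "semscan_config_error")
  if (length(loadings) != 4 || any(loadings <= 0) || any(loadings >= 1))
    stop_semscan("exactly 4 loadings in (0, 1) are required (standardized scale)",
                 "semscan_config_error")
  if (length(likert_thresholds) != 6 || any(diff(likert_thresholds) <= 0))
    stop_semscan("likert_thresholds must be 6 strictly increasing cut points",
                 "semscan_config_error")
  if (!is.null(causal_variants)) {
    causal_variants <- as.data.frame(causal_variants)
    if (!all(c("index", "beta") %in% names(causal_variants)))
      stop_semscan("causal_variants needs columns 'index' and 'beta'",
                   "semscan_config_error")
    if (any(causal_variants$index < 1) ||
        any(causal_variants$index > n_variants) ||
        any(causal_variants$index != round(causal_variants$index)))
      stop_semscan("causal variant indices must be integers in 1..n_variants",
                   "semscan_config_error")
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_variants = as.integer(n_variants),
                 maf_range = as.numeric(maf_range),
                 ld_block_size = as.integer(ld_block_size),
                 ld_rho = as.numeric(ld_rho),
                 causal_variants = causal_variants,
                 loadings = as.numeric(loadings),
                 covariate_effects = covariate_effects,
                 likert_thresholds = as.numeric(likert_thresholds),
                 likert_shift = likert_shift,
                 likert_scale = likert_scale,
                 item_noise_sd = item_noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Haplotype sampler: per block, a latent AR(1) Gaussian process per haplotype is
# thresholded at qnorm(maf) so each variant is in HWE with the requested
# frequency while adjacent variants keep correlation ~ ld_rho^distance.
.sample_dosages <- function(mafs, block, rho, n) {
  m <- length(mafs)
  dos <- matrix(0L, n, m)
  thr <- qnorm(mafs)
  for (b in unique(block)) {
    idx <- which(block == b)
    for (hap in 1:2) {
      z <- matrix(0, n, length(idx))
      z[, 1] <- rnorm(n)
      if (length(idx) > 1) {
        w <- sqrt(1 - rho^2)
        for (j in 2:length(idx)) z[, j] <- rho * z[, j - 1] + w * rnorm(n)
      }
      dos[, idx] <- dos[, idx] + (z < rep(thr[idx], each = n))
    }
  }
  dos
}

#' Simulate a genotype dataset
#'
#' Draws per-variant minor allele frequencies from `config$maf_range`, then
#' samples two haplotypes per subject from a block-wise Gaussian copula with
#' first-order autoregressive correlation `ld_rho`, thresholded to alleles.
#' Every variant is in Hardy-Weinberg equilibrium; LD decays with within-block
#' distance and is absent across blocks.
#'
#' @param config a [sim_config()].
#' @return an object of class `geno_ds`: a list with `dosage` (samples x
#'   variants integer matrix in 0/1/2), `variants` (chrom, pos, id, ref, alt,
#'   maf, block) and `samples` data frames.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  m <- config$n_variants; n <- config$n_samples
  mafs <- runif(m, config$maf_range[1], config$maf_range[2])
  block <- ceiling(seq_len(m) / config$ld_block_size)
  dos <- .sample_dosages(mafs, block, config$ld_rho, n)
  pos <- cumsum(sample(500:1500, m, replace = TRUE))
  ids <- sprintf("var%05d", seq_len(m))
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  variants <- data.frame(chrom = "1", pos = pos, id = ids, ref = ref,
                         alt = unname(alt), maf = mafs, block = block,
                         stringsAsFactors = FALSE)
  colnames(dos) <- ids
  sample_ids <- sprintf("S%04d", seq_len(n))
  rownames(dos) <- sample_ids
  structure(list(dosage = dos, variants = variants,
                 samples = data.frame(id = sample_ids, stringsAsFactors = FALSE)),
            class = "geno_ds")
}

#' @export
print.geno_ds <- function(x, ...) {
  cat("Genotype dataset:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  cat("  missing rate:", signif(mean(is.na(x$dosage)), 3), "\n")
  invisible(x)
}

# map of questionnaire items to the four symptom categories
#' Default item-to-category map
#'
#' Items q1–q3 are asthenopic, q4–q7 ocular-surface-related, q8–q9 visual and
#' q10–q14 extra-ocular.
#' @return named character vector: item id -> category label.
#' @export
default_item_map <- function() {
  c(q1 = "asthenopic", q2 = "asthenopic", q3 = "asthenopic",
    q4 = "ocular_surface", q5 = "ocular_surface", q6 = "ocular_surface",
    q7 = "ocular_surface",
    q8 = "visual", q9 = "visual",
    q10 = "extra_ocular", q11 = "extra_ocular", q12 = "extra_ocular",
    q13 = "extra_ocular", q14 = "extra_ocular")
}

.likert <- function(v, cuts) findInterval(v, cuts) + 1L

#' Simulate questionnaire phenotypes from the one-factor model run forward
#'
#' The latent trait is `F = sum(beta * centered dosage) + covariate effects +
#' noise`, standardized.  Continuous category scores are `y_k = gamma_k * F +
#' sqrt(1 - gamma_k^2) * e_k`.  Each item score adds item-specific noise to its
#' category score; the low-load ("before") response thresholds a baseline
#' propensity and the high-load ("after") response thresholds the same
#' propensity shifted by `likert_shift + likert_scale * item score`, so the
#' delta score recovers the latent signal up to quantization.
#'
#' @param genotypes a `geno_ds` from [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @return list with `questionnaire` (subject id plus `q*_before`/`q*_after`
#'   columns), `covariates` (id, age, sex) and `truth` (latent scores, causal
#'   map, true loadings, continuous category scores).
#' @export
simulate_phenotypes <- function(genotypes, config) {
  stopifnot(inherits(genotypes, "geno_ds"), inherits(config, "sim_config"))
  n <- nrow(genotypes$dosage)
  set.seed(derive_seed(config$seed, 2L))
  age <- pmin(79L, pmax(20L, as.integer(round(rnorm(n, 49.3, 12)))))
  sex <- rbinom(n, 1L, 0.505)  # 1 = male
  eff <- config$covariate_effects
  lat <- rnorm(n)
  lat <- lat + (eff["age"] %||% 0) * as.numeric(scale(age)) +
    (eff["sex"] %||% 0) * as.numeric(scale(sex))
  cv <- config$causal_variants
  if (!is.null(cv) && nrow(cv) > 0) {
    for (r in seq_len(nrow(cv))) {
      g <- genotypes$dosage[, cv$index[r]]
      lat <- lat + cv$beta[r] * (g - mean(g, na.rm = TRUE))
    }
  }
  lat <- as.numeric(scale(lat))
  gam <- config$loadings
  ycat <- sapply(1:4, function(k) gam[k] * lat + sqrt(1 - gam[k]^2) * rnorm(n))
  colnames(ycat) <- unique(unname(default_item_map()))
  imap <- default_item_map()
  items <- names(imap)
  before <- after <- matrix(0L, n, length(items),
                            dimnames = list(NULL, items))
  catlab <- colnames(ycat)
  for (j in seq_along(items)) {
    k <- match(imap[[j]], catlab)
    a_j <- ycat[, k] + config$item_noise_sd * rnorm(n)
    u <- rnorm(n)
    before[, j] <- .likert(u, config$likert_thresholds)
    after[, j] <- .likert(u + config$likert_shift + config$likert_scale * a_j,
                          config$likert_thresholds)
  }
  quest <- data.frame(id = genotypes$samples$id,
                      setNames(as.data.frame(before), paste0(items, "_before")),
                      setNames(as.data.frame(after), paste0(items, "_after")),
                      stringsAsFactors = FALSE)
  covars <- data.frame(id = genotypes$samples$id, age = age, sex = sex,
                       stringsAsFactors = FALSE)
  truth <- list(latent_scores = lat,
                causal_map = cv,
                true_loadings = setNames(gam, catlab),
                category_truth = ycat)
  list(questionnaire = quest, covariates = covars, truth = truth)
}

#' Simulate eQTL summary statistics for a colocalization scenario
#'
#' Draws an independent expression cohort on the same variant panel (same
#' frequencies and LD structure) and regresses a simulated expression trait on
#' each variant.  Under `"shared"` the expression causal variant is the GWAS
#' causal variant from `config`; under `"distinct"` it is a different variant
#' in the same LD neighbourhood; under `"null"` expression is pure noise.
#'
#' @param genotypes `geno_ds` providing the variant panel.
#' @param scenario one of `"shared"`, `"distinct"`, `"null"`.
#' @param config the [sim_config()] whose first causal variant anchors the
#'   scenario.
#' @param n_eqtl expression-study sample size.
#' @param effect standardized effect of the causal variant on expression.
#' @param gene,tissue labels copied to the output.
#' @return data frame: id, chrom, pos, gene, tissue, beta, se, p, maf, n.
#' @export
simulate_eqtl_summary <- function(genotypes, scenario, config,
                                  n_eqtl = 500L, effect = 0.8,
                                  gene = "GENE1", tissue = "tissue") {
  stopifnot(inherits(genotypes, "geno_ds"), inherits(config, "sim_config"))
  if (!scenario %in% c("shared", "distinct", "null"))
    stop_semscan(sprintf("unknown scenario '%s'", scenario),
                 "semscan_config_error")
  v <- genotypes$variants
  set.seed(derive_seed(config$seed, 17L))
  dos <- .sample_dosages(v$maf, v$block, config$ld_rho %||% 0, n_eqtl)
  causal <- NA_integer_
  if (scenario != "null") {
    cv <- config$causal_variants
    if (is.null(cv) || nrow(cv) == 0)
      stop_semscan("scenario needs a causal variant in the config",
                   "semscan_config_error")
    gidx <- cv$index[1]
    if (scenario == "shared") {
      causal <- gidx
    } else {
      # a different variant in the same block, as far from the lead as possible
      same_block <- setdiff(which(v$block == v$block[gidx]), gidx)
      if (length(same_block) == 0) same_block <- setdiff(seq_len(nrow(v)), gidx)
      causal <- same_block[which.max(abs(same_block - gidx))]
    }
  }
  expr <- rnorm(n_eqtl)
  if (!is.na(causal)) {
    g <- dos[, causal]
    expr <- expr + effect * (g - mean(g)) / max(sd(g), 1e-12)
  }
  # per-variant simple linear regression, vectorized
  gc_ <- scale(dos, scale = FALSE)
  ec <- expr - mean(expr)
  sxx <- colSums(gc_^2)
  sxx[sxx == 0] <- NA
  beta <- as.numeric(crossprod(gc_, ec)) / sxx
  res_ss <- sum(ec^2) - beta^2 * sxx
  se <- sqrt(pmax(res_ss, 0) / ((n_eqtl - 2) * sxx))
  z <- beta / se
  data.frame(id = v$id, chrom = v$chrom, pos = v$pos,
             gene = gene, tissue = tissue,
             beta = beta, se = se, p = 2 * pnorm(-abs(z)),
             maf = pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2),
             n = n_eqtl, stringsAsFactors = FALSE)
}

#' Write a genotype dataset as plain-text VCF 4.2
#'
#' Dosages are encoded as unphased GT (`0/0`, `0/1`, `1/1`); missing dosages
#' as `./.`.
#'
#' @param genotypes a `geno_ds`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  gt_map <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow(v), nrow(genotypes$dosage))
  dos <- t(genotypes$dosage)
  ok <- !is.na(dos)
  gt[ok] <- gt_map[dos[ok] + 1L]
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##source=semscan",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", genotypes$samples$id), collapse = "\t"))
  ok <- tryCatch({ writeLines(c(header, body), path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop_semscan(sprintf("failed writing VCF to '%s': %s", path,
                         conditionMessage(ok)), "semscan_io_error")
  invisible(path)
}

#' Read a VCF into a genotype dataset
#'
#' Uses vcfR to parse; the dosage is the ALT-allele count of the GT field,
#' `NA` for missing genotypes.
#'
#' @param path VCF path (plain or bgzipped).
#' @return a `geno_ds`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path))
    stop_semscan(sprintf("VCF not found: '%s'", path), "semscan_io_error")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  dos <- t(dos)
  colnames(dos) <- fix$ID
  rownames(dos) <- colnames(gt)
  af <- colMeans(dos, na.rm = TRUE) / 2
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         id = fix$ID, ref = fix$REF, alt = fix$ALT,
                         maf = pmin(af, 1 - af), block = NA_integer_,
                         stringsAsFactors = FALSE)
  structure(list(dosage = dos, variants = variants,
                 samples = data.frame(id = colnames(gt),
                                      stringsAsFactors = FALSE)),
            class = "geno_ds")
}

#' Export a simulated dataset to disk
#'
#' Writes the genotypes as VCF and the questionnaire, covariates and ground
#' truth as tab-delimited files with header rows; these round-trip through
#' [read_vcf()] / [read.table()].
#'
#' @param genotypes `geno_ds`.
#' @param phenotypes the list returned by [simulate_phenotypes()].
#' @param dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
export_dataset <- function(genotypes, phenotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             questionnaire = file.path(dir, "questionnaire.tsv"),
             covariates = file.path(dir, "covariates.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(genotypes, paths[["vcf"]])
  write.table(phenotypes$questionnaire, paths[["questionnaire"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(phenotypes$covariates, paths[["covariates"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- data.frame(id = phenotypes$questionnaire$id,
                   latent = phenotypes$truth$latent_scores,
                   phenotypes$truth$category_truth,
                   stringsAsFactors = FALSE)
  write.table(tr, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}
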