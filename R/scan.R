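# Genome-wide driver: per-variant SEM tests, genomic control, single-trait
# comparison scans, LD-based lead/locus definition and plot-ready exports.

CHI2_1_MEDIAN <- 0.4549364  # median of the chi-square distribution, df = 1

#' SEM-based multi-trait genome-wide scan
#'
#' Fits [fit_variant_model()] for every polymorphic variant, warm-starting
#' from the no-SNP measurement fit, then applies [genomic_control()].
#' Monomorphic and non-converged variants are excluded and counted.
#'
#' @param genotypes a `geno_ds` (post-QC).
#' @param categories data frame of the four category scores (plus optional
#'   `id`, ignored for fitting; row order must match the genotypes).
#' @param covariates optional numeric covariate data frame (e.g. age, sex,
#'   PCs).
#' @param gc apply genomic control (default TRUE).
#' @return an `assoc_table`: data frame with chrom, pos, id, ref, alt, maf, n,
#'   beta, se, z, p_raw, p_gc, sorted by (chrom, pos); attributes `lambda_gc`
#'   and `skipped`.
#' @export
run_scan <- function(genotypes, categories, covariates = NULL, gc = TRUE) {
  stopifnot(inherits(genotypes, "geno_ds"))
  Y <- as.matrix(categories[, vapply(as.data.frame(categories), is.numeric,
                                     TRUE), drop = FALSE])
  base <- fit_one_factor(Y, covariates = covariates)
  m <- ncol(genotypes$dosage)
  res <- vector("list", m)
  skipped <- character(0)
  for (j in seq_len(m)) {
    g <- genotypes$dosage[, j]
    fit <- tryCatch(fit_variant_model(Y, g, covariates, start = base),
                    semscan_monomorphic = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      skipped <- c(skipped, genotypes$variants$id[j])
      next
    }
    res[[j]] <- c(beta = fit$beta, se = fit$se, z = fit$z, p = fit$p,
                  n = fit$n_used)
  }
  keep <- !vapply(res, is.null, TRUE)
  if (!any(keep))
    stop_semscan("no variant produced a valid association test",
                 "semscan_empty_result")
  stats <- do.call(rbind, res[keep])
  v <- genotypes$variants[keep, , drop = FALSE]
  tab <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
                    ref = v$ref, alt = v$alt, maf = v$maf,
                    n = as.integer(stats[, "n"]),
                    beta = stats[, "beta"], se = stats[, "se"],
                    z = stats[, "z"], p_raw = stats[, "p"],
                    p_gc = stats[, "p"], stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos), ]
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  attr(tab, "lambda_gc") <- NA_real_
  class(tab) <- c("assoc_table", "data.frame")
  if (gc) tab <- genomic_control(tab)
  tab
}

#' Genomic control
#'
#' `lambda_GC = median(z^2) / 0.4549364` (the chi-square df=1 median).  When
#' `lambda_GC > 1` each statistic is deflated to `z^2 / lambda_GC` and `p_gc`
#' recomputed from the chi-square df=1 tail; otherwise `p_gc = p_raw`.
#'
#' @param table an `assoc_table` with >= 100 valid z statistics.
#' @return the table with `p_gc` filled and attribute `lambda_gc` set.
#' @export
genomic_control <- function(table) {
  z2 <- table$z^2
  z2 <- z2[is.finite(z2)]
  if (length(z2) < 100)
    stop_semscan("genomic control needs >= 100 variants with valid z",
                 "semscan_insufficient_data")
  lambda <- median(z2) / CHI2_1_MEDIAN
  if (lambda > 1) {
    table$p_gc <- pchisq(table$z^2 / lambda, df = 1, lower.tail = FALSE)
  } else {
    table$p_gc <- table$p_raw
  }
  attr(table, "lambda_gc") <- lambda
  table
}

#' Composite LD r-squared between two variants
#'
#' Squared Pearson correlation of dosages over pairwise-complete samples.
#'
#' @param g1,g2 dosage vectors.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2)
    stop_semscan("need >= 2 complete pairs", "semscan_insufficient_data")
  if (var(g1[ok]) == 0 || var(g2[ok]) == 0)
    stop_semscan("LD undefined for a monomorphic variant",
                 "semscan_undefined_ld")
  cor(g1[ok], g2[ok])^2
}

#' Define loci around lead variants
#'
#' Variants with `p_gc` (or `p_raw`) below `p_threshold` are lead candidates.
#' Working best-p-first, each lead absorbs the panel variants within
#' `window_kb` whose r-squared with it exceeds `r2_threshold`; remaining
#' candidates that fall inside the new locus membership are dropped
#' (greedy deduplication).  A lead with no correlated partner yields a
#' single-position locus (`start == end == lead position`).
#'
#' @param table an `assoc_table`.
#' @param panel `geno_ds` supplying LD (defaults should be the study
#'   genotypes; an external reference panel may be given).
#' @param p_threshold suggestive significance level (default 1e-5).
#' @param r2_threshold LD threshold for locus membership (default 0.6).
#' @param window_kb half-window searched around the lead (default 500).
#' @param use which p-value column defines leads: "p_gc" or "p_raw".
#' @return data frame of loci: lead_id, chrom, start, end, n_members, lead_p,
#'   with member ids in the list column `members`.
#' @export
define_loci <- function(table, panel, p_threshold = 1e-5, r2_threshold = 0.6,
                        window_kb = 500, use = c("p_gc", "p_raw")) {
  use <- match.arg(use)
  cand <- table[is.finite(table[[use]]) & table[[use]] < p_threshold, ]
  if (nrow(cand) == 0)
    return(data.frame(lead_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_members = integer(0), lead_p = numeric(0)))
  cand <- cand[order(cand[[use]]), ]
  pv <- panel$variants
  loci <- list()
  used <- character(0)
  for (i in seq_len(nrow(cand))) {
    lead <- cand[i, ]
    if (lead$id %in% used) next
    k <- match(lead$id, pv$id)
    if (is.na(k)) {
      k <- which(pv$chrom == lead$chrom & pv$pos == lead$pos &
                   pv$ref == lead$ref & pv$alt == lead$alt)[1]
    }
    if (is.na(k)) {
      warning(sprintf("lead %s absent from LD panel; single-position locus",
                      lead$id))
      members <- lead$id
      start <- end <- lead$pos
    } else {
      win <- which(pv$chrom == pv$chrom[k] &
                     abs(pv$pos - pv$pos[k]) <= window_kb * 1000)
      g0 <- panel$dosage[, k]
      r2 <- vapply(win, function(j) {
        tryCatch(ld_r2(g0, panel$dosage[, j]), semscan_error = function(e) 0)
      }, 0)
      mem <- win[r2 > r2_threshold]
      if (!(k %in% mem)) mem <- c(k, mem)
      members <- pv$id[mem]
      start <- min(pv$pos[mem]); end <- max(pv$pos[mem])
    }
    used <- union(used, members)
    loci[[length(loci) + 1]] <-
      list(lead_id = lead$id, chrom = lead$chrom, start = start, end = end,
           n_members = length(members), lead_p = lead[[use]],
           members = members)
  }
  out <- data.frame(lead_id = vapply(loci, `[[`, "", "lead_id"),
                    chrom = vapply(loci, `[[`, "", "chrom"),
                    start = vapply(loci, function(l) as.integer(l$start), 1L),
                    end = vapply(loci, function(l) as.integer(l$end), 1L),
                    n_members = vapply(loci, function(l) l$n_members, 1L),
                    lead_p = vapply(loci, function(l) l$lead_p, 1),
                    stringsAsFactors = FALSE)
  out$members <- lapply(loci, `[[`, "members")
  out
}

#' Single-trait genome-wide scan
#'
#' Ordinary least squares of one category score on dosage plus covariates,
#' with a Wald t-test per variant; same output format as [run_scan()].
#'
#' @param genotypes `geno_ds`.
#' @param trait numeric vector (one category score per subject).
#' @param covariates optional numeric covariates.
#' @param gc apply genomic control.
#' @return an `assoc_table`.
#' @export
single_trait_scan <- function(genotypes, trait, covariates = NULL, gc = TRUE) {
  stopifnot(inherits(genotypes, "geno_ds"))
  y <- as.numeric(trait)
  C <- if (is.null(covariates)) matrix(1, length(y), 1) else
    cbind(1, as.matrix(covariates[, vapply(as.data.frame(covariates),
                                           is.numeric, TRUE), drop = FALSE]))
  m <- ncol(genotypes$dosage)
  res <- vector("list", m)
  skipped <- character(0)
  for (j in seq_len(m)) {
    g <- genotypes$dosage[, j]
    ok <- !is.na(g) & !is.na(y) & complete.cases(C)
    if (sum(ok) < ncol(C) + 2 || var(g[ok]) == 0) {
      skipped <- c(skipped, genotypes$variants$id[j])
      next
    }
    X <- cbind(g[ok], C[ok, , drop = FALSE])
    qx <- qr(X)
    cf <- qr.coef(qx, y[ok])
    e <- y[ok] - X %*% cf
    df <- sum(ok) - qx$rank
    sigma2 <- sum(e^2) / df
    XtXinv <- chol2inv(qr.R(qx))
    se <- sqrt(sigma2 * XtXinv[1, 1])
    tstat <- cf[1] / se
    res[[j]] <- c(beta = cf[1], se = se, z = tstat,
                  p = 2 * stats::pt(-abs(tstat), df), n = sum(ok))
  }
  keep <- !vapply(res, is.null, TRUE)
  if (!any(keep))
    stop_semscan("no variant produced a valid association test",
                 "semscan_empty_result")
  stats <- do.call(rbind, res[keep])
  v <- genotypes$variants[keep, , drop = FALSE]
  tab <- data.frame(chrom = v$chrom, pos = v$pos, id = v$id,
                    ref = v$ref, alt = v$alt, maf = v$maf,
                    n = as.integer(stats[, "n"]),
                    beta = stats[, "beta"], se = stats[, "se"],
                    z = stats[, "z"], p_raw = stats[, "p"],
                    p_gc = stats[, "p"], stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos), ]
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  attr(tab, "lambda_gc") <- NA_real_
  class(tab) <- c("assoc_table", "data.frame")
  if (gc) tab <- genomic_control(tab)
  tab
}

#' Export plot-ready tables for Manhattan and Q-Q displays
#'
#' Writes `manhattan.tsv` (cumulative genome position, -log10 p),
#' `qq.tsv` (expected vs observed -log10 p) and `plot_metadata.json`
#' (significance thresholds: genome-wide 5.0e-8, suggestive 1.0e-5).
#'
#' @param table an `assoc_table`.
#' @param dir output directory.
#' @param use p-value column to plot.
#' @return named vector of paths, invisibly.
#' @export
export_plots_data <- function(table, dir, use = "p_gc") {
  if (nrow(table) == 0)
    stop_semscan("empty association table", "semscan_empty_result")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- table[[use]]
  # cumulative position across chromosomes in input (chrom, pos) order
  offs <- 0; cum <- numeric(nrow(table))
  for (ch in unique(table$chrom)) {
    i <- table$chrom == ch
    cum[i] <- table$pos[i] + offs
    offs <- offs + max(table$pos[i])
  }
  man <- data.frame(chrom = table$chrom, pos = table$pos, cum_pos = cum,
                    id = table$id, neglog10p = -log10(p))
  o <- order(p)
  n <- length(p)
  qq <- data.frame(expected = -log10((seq_len(n) - 0.5) / n),
                   observed = -log10(p[o]), id = table$id[o])
  paths <- c(manhattan = file.path(dir, "manhattan.tsv"),
             qq = file.path(dir, "qq.tsv"),
             metadata = file.path(dir, "plot_metadata.json"))
  write.table(man, paths[["manhattan"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(qq, paths[["qq"]], sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(genome_wide_threshold = 5.0e-8,
                            suggestive_threshold = 1.0e-5,
                            lambda_gc = attr(table, "lambda_gc"),
                            n_variants = nrow(table)),
                       paths[["metadata"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Manhattan plot
#' @param table an `assoc_table`.
#' @param use p-value column.
#' @param ... passed to [graphics::plot()].
#' @export
plot_manhattan <- function(table, use = "p_gc", ...) {
  offs <- 0; cum <- numeric(nrow(table))
  for (ch in unique(table$chrom)) {
    i <- table$chrom == ch
    cum[i] <- table$pos[i] + offs
    offs <- offs + max(table$pos[i])
  }
  graphics::plot(cum, -log10(table[[use]]), pch = 20, cex = 0.5,
                 xlab = "cumulative position", ylab = "-log10 p", ...)
  graphics::abline(h = -log10(5e-8), col = "red")
  graphics::abline(h = -log10(1e-5), col = "blue")
  invisible(NULL)
}

#' Q-Q plot of scan p-values
#' @param table an `assoc_table`.
#' @param use p-value column.
#' @param ... passed to [graphics::plot()].
#' @export
plot_qq <- function(table, use = "p_gc", ...) {
  p <- sort(table[[use]])
  n <- length(p)
  e <- -log10((seq_len(n) - 0.5) / n)
  graphics::plot(e, -log10(p), pch = 20, cex = 0.5,
                 xlab = "expected -log10 p", ylab = "observed -log10 p", ...)
  graphics::abline(0, 1, col = "grey")
  invisible(NULL)
}
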