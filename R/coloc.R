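# Bayesian colocalization of GWAS and eQTL signals in a region:
# per-variant Wakefield approximate Bayes factors, five-hypothesis sums
# (H0 no signal, H1 GWAS only, H2 eQTL only, H3 two distinct causal variants,
# H4 one shared causal variant) and posterior probabilities PPH0..PPH4,
# accumulated in log space for numerical stability.

#' Wakefield log approximate Bayes factor
#'
#' With `V = se^2`, `r = W / (V + W)` (`W = prior_sd^2`) and `z = beta / se`,
#' `lABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s), > 0.
#' @param prior_sd prior standard deviation of the true effect (default 0.15,
#'   the quantitative-trait convention).
#' @return log approximate Bayes factor(s) in favour of a real effect.
#' @export
wakefield_labf <- function(beta, se, prior_sd = 0.15) {
  if (any(se <= 0) || prior_sd <= 0)
    stop_semscan("se and prior_sd must be positive", "semscan_input_error")
  V <- se^2
  r <- prior_sd^2 / (V + prior_sd^2)
  z <- beta / se
  0.5 * (log(1 - r) + r * z^2)
}

#' Log approximate Bayes factor from p-value summary data
#'
#' For summary statistics lacking beta/se: `z^2` from the inverse-normal of
#' `p/2` (sign unknown and unused) and the sampling variance approximated by
#' `V = 1 / (2 n maf (1 - maf))` for a standardized quantitative trait.
#'
#' @param p p-value(s) in (0, 1]; exact zeros are clamped to the smallest
#'   positive double with a warning.
#' @param maf minor allele frequency in (0, 0.5].
#' @param n study sample size.
#' @param prior_sd as in [wakefield_labf()].
#' @return log approximate Bayes factor(s).
#' @export
labf_from_pvalues <- function(p, maf, n, prior_sd = 0.15) {
  if (any(p < 0) || any(p > 1))
    stop_semscan("p-values must lie in (0, 1]", "semscan_input_error")
  if (any(maf <= 0) || any(maf > 0.5))
    stop_semscan("maf must lie in (0, 0.5]", "semscan_input_error")
  if (any(n < 2)) stop_semscan("n must be >= 2", "semscan_input_error")
  if (any(p == 0)) {
    warning("p = 0 clamped to the smallest positive representable value")
    p[p == 0] <- .Machine$double.xmin
  }
  z <- qnorm(p / 2, lower.tail = FALSE)
  V <- 1 / (2 * n * maf * (1 - maf))
  se <- sqrt(V)
  wakefield_labf(z * se, se, prior_sd)
}

.region_labf <- function(x, prior_sd) {
  if (all(c("beta", "se") %in% names(x)) && !anyNA(x$beta) && !anyNA(x$se)) {
    wakefield_labf(x$beta, x$se, prior_sd)
  } else if (all(c("p", "maf", "n") %in% names(x))) {
    labf_from_pvalues(x$p, x$maf, x$n, prior_sd)
  } else {
    stop_semscan("region summary needs (beta, se) or (p, maf, n)",
                 "semscan_input_error")
  }
}

#' Colocalization posteriors PPH0-PPH4
#'
#' Per-hypothesis evidence over the shared variants (log-space sums):
#' `S1 = p1 * sum(exp(lABF_gwas))`, `S2 = p2 * sum(exp(lABF_eqtl))`,
#' `S3 = p1 p2 * (sum_g * sum_e - sum(exp(lABF_g + lABF_e)))`,
#' `S4 = p12 * sum(exp(lABF_g + lABF_e))`, `S0 = 1`; posteriors are the
#' normalized sums.
#'
#' @param gwas,eqtl data frames with column `id` plus either (`beta`, `se`)
#'   or (`p`, `maf`, `n`).
#' @param p1,p2 prior probabilities a variant is causal for the GWAS trait /
#'   the expression trait (defaults 1e-4).
#' @param p12 prior probability a variant is causal for both (default 1e-5).
#' @param prior_sd effect prior SD for the Bayes factors.
#' @return object of class `coloc_result`: `posteriors` (pph0..pph4, summing
#'   to 1 within 1e-12), `n_snps`, `priors`, per-variant `labf` table.
#' @export
coloc_posteriors <- function(gwas, eqtl, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             prior_sd = 0.15) {
  if (anyDuplicated(gwas$id) || anyDuplicated(eqtl$id))
    stop_semscan("variant ids must be unique within each summary",
                 "semscan_input_error")
  shared <- intersect(gwas$id, eqtl$id)
  if (length(shared) == 0)
    stop_semscan(sprintf(
      "no shared variants (gwas has %d ids, eqtl %d; e.g. gwas '%s' vs eqtl '%s')",
      length(gwas$id), length(eqtl$id), head(gwas$id, 1), head(eqtl$id, 1)),
      "semscan_empty_region")
  g <- gwas[match(shared, gwas$id), , drop = FALSE]
  e <- eqtl[match(shared, eqtl$id), , drop = FALSE]
  lg <- .region_labf(g, prior_sd)
  le <- .region_labf(e, prior_sd)
  sum_g <- logsumexp(lg)
  sum_e <- logsumexp(le)
  sum_ge <- logsumexp(lg + le)
  logS <- c(h0 = 0,
            h1 = log(p1) + sum_g,
            h2 = log(p2) + sum_e,
            h3 = log(p1) + log(p2) + logdiffexp(sum_g + sum_e, sum_ge),
            h4 = log(p12) + sum_ge)
  post <- exp(logS - logsumexp(logS))
  post <- post / sum(post)
  structure(list(posteriors = setNames(post, paste0("pph", 0:4)),
                 n_snps = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = prior_sd,
                 labf = data.frame(id = shared, labf_gwas = lg,
                                   labf_eqtl = le, stringsAsFactors = FALSE)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Colocalization over", x$n_snps, "shared variants\n")
  print(round(x$posteriors, 4))
  cat(sprintf("  priors p1 = %g, p2 = %g, p12 = %g\n",
              x$priors["p1"], x$priors["p2"], x$priors["p12"]))
  invisible(x)
}

#' Extract the summary statistics of a locus region
#'
#' Variants with `locus$start - flank <= pos <= locus$end + flank` on the
#' locus chromosome; the left edge is clamped at position 1.
#'
#' @param stats summary-statistics data frame with `chrom` and `pos`.
#' @param locus one row of [define_loci()] output (or a list with chrom,
#'   start, end).
#' @param flank_kb flank width in kb (default 100).
#' @return the row subset of `stats`.
#' @export
extract_region <- function(stats, locus, flank_kb = 100) {
  lo <- max(locus$start - flank_kb * 1000, 1)
  hi <- locus$end + flank_kb * 1000
  if (!any(stats$chrom == locus$chrom))
    stop_semscan(sprintf("chromosome %s absent from summary statistics",
                         locus$chrom), "semscan_empty_region")
  out <- stats[stats$chrom == locus$chrom & stats$pos >= lo &
                 stats$pos <= hi, , drop = FALSE]
  if (nrow(out) == 0)
    stop_semscan(sprintf("no variants in region %s:%d-%d", locus$chrom,
                         lo, hi), "semscan_empty_region")
  out
}

#' Batch colocalization of loci against eQTL panels
#'
#' Evaluates every locus against every eQTL panel over a +/- `flank_kb`
#' window; reports PPH4 per combination, flagged when above the reporting
#' threshold (default 0.5) and "strong" above 0.75.
#'
#' @param gwas_table an `assoc_table` (needs beta, se or p, maf, n).
#' @param loci output of [define_loci()].
#' @param eqtl_panels named list of eQTL summary data frames (id, chrom, pos,
#'   beta, se or p/maf/n; optional gene/tissue columns are echoed).
#' @param flank_kb region flank (default 100).
#' @param report_threshold,strong_threshold PPH4 reporting cutoffs.
#' @param ... priors passed to [coloc_posteriors()].
#' @return data frame: locus lead, panel, pph0..pph4, n_snps, reported,
#'   strong.
#' @export
coloc_batch <- function(gwas_table, loci, eqtl_panels, flank_kb = 100,
                        report_threshold = 0.5, strong_threshold = 0.75, ...) {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    gr <- tryCatch(extract_region(gwas_table, locus, flank_kb),
                   semscan_empty_region = function(e) NULL)
    if (is.null(gr)) next
    for (nm in names(eqtl_panels)) {
      er <- tryCatch(extract_region(eqtl_panels[[nm]], locus, flank_kb),
                     semscan_empty_region = function(e) NULL)
      if (is.null(er)) next
      cr <- tryCatch(coloc_posteriors(gr, er, ...),
                     semscan_empty_region = function(e) NULL)
      if (is.null(cr)) next
      rows[[length(rows) + 1]] <- data.frame(
        lead_id = locus$lead_id, chrom = locus$chrom,
        start = locus$start, end = locus$end, panel = nm,
        t(cr$posteriors), n_snps = cr$n_snps,
        reported = cr$posteriors["pph4"] > report_threshold,
        strong = cr$posteriors["pph4"] > strong_threshold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(lead_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      panel = character(0), pph0 = numeric(0),
                      pph1 = numeric(0), pph2 = numeric(0),
                      pph3 = numeric(0), pph4 = numeric(0),
                      n_snps = integer(0), reported = logical(0),
                      strong = logical(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
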