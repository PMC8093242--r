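# Variant/sample QC: Hardy-Weinberg exact test, call-rate/MAF/HWE variant
# filters, PLINK-convention method-of-moments IBD, and projection PCA for
# population stratification.

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the allele counts: the p-value sums the
#' probabilities of all heterozygote counts whose conditional probability does
#' not exceed that of the observed count (probability ordering, no mid-p).
#' Probabilities follow the standard recurrence over heterozygote counts of the
#' same parity.
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(c(n_AA, n_Aa, n_aa) != round(c(n_AA, n_Aa, n_aa))))
    stop_semscan("genotype counts must be non-negative integers",
                 "semscan_input_error")
  n <- n_AA + n_Aa + n_aa
  if (n < 1)
    stop_semscan("all-zero genotype counts", "semscan_input_error")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa   # rare allele count
  # attainable heterozygote counts share the parity of n_rare
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  if (length(hets) == 1) return(1.0)
  # unnormalized log-probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_hom_rare(h) * n_hom_common(h) / ((h+2)*(h+1))
  lp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    hom_r <- (n_rare - h) / 2
    hom_c <- (2 * n - n_rare - h) / 2
    lp[i] <- lp[i - 1] + log(4 * hom_r * hom_c) - log((h + 2) * (h + 1))
  }
  lp <- lp - logsumexp(lp)
  obs <- match(n_Aa, hets)
  if (is.na(obs))
    stop_semscan("heterozygote count inconsistent with allele counts",
                 "semscan_input_error")
  p <- sum(exp(lp[lp <= lp[obs] + 1e-12]))
  min(p, 1.0)
}

#' QC thresholds
#'
#' @param min_call_rate minimum per-variant call rate.
#' @param min_maf minimum minor allele frequency.
#' @param max_ibd PI_HAT above which a sample pair is flagged as related.
#' @param min_hwe_p Hardy-Weinberg exact-test p-value below which a variant is
#'   removed.
#' @return a validated `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_call_rate = 0.95, min_maf = 0.01,
                          max_ibd = 0.1875, min_hwe_p = 1e-6) {
  vals <- c(min_call_rate, min_maf, max_ibd, min_hwe_p)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1))
    stop_semscan("QC thresholds must lie in [0, 1]", "semscan_config_error")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 max_ibd = max_ibd, min_hwe_p = min_hwe_p),
            class = "qc_thresholds")
}

#' Variant-level quality control
#'
#' Applies the filters sequentially in the fixed order call rate, then MAF,
#' then Hardy-Weinberg exact test, so each removal count is conditional on the
#' previous filters.
#'
#' @param genotypes a `geno_ds`.
#' @param thresholds a [qc_thresholds()].
#' @return list with `genotypes` (filtered `geno_ds`) and `report` (counts per
#'   filter, class `qc_report`).
#' @export
variant_qc <- function(genotypes, thresholds = qc_thresholds()) {
  stopifnot(inherits(genotypes, "geno_ds"))
  dos <- genotypes$dosage
  m0 <- ncol(dos)
  call_rate <- colMeans(!is.na(dos))
  keep <- call_rate >= thresholds$min_call_rate
  n_call <- sum(!keep)
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  fail_maf <- keep & (is.na(maf) | maf < thresholds$min_maf)
  n_maf <- sum(fail_maf)
  keep <- keep & !fail_maf
  hwe_p <- rep(NA_real_, m0)
  for (j in which(keep)) {
    g <- dos[, j]
    hwe_p[j] <- hwe_exact_test(sum(g == 0, na.rm = TRUE),
                               sum(g == 1, na.rm = TRUE),
                               sum(g == 2, na.rm = TRUE))
  }
  fail_hwe <- keep & hwe_p <= thresholds$min_hwe_p
  n_hwe <- sum(fail_hwe)
  keep <- keep & !fail_hwe
  out <- genotypes
  out$dosage <- dos[, keep, drop = FALSE]
  out$variants <- genotypes$variants[keep, , drop = FALSE]
  report <- structure(list(variants_in = m0, variants_out = sum(keep),
                           removed = c(call_rate = n_call, maf = n_maf,
                                       hwe = n_hwe),
                           thresholds = thresholds),
                      class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Variant QC:", x$variants_in, "->", x$variants_out, "variants\n")
  cat(sprintf("  removed: call rate %d, MAF %d, HWE %d\n",
              x$removed[["call_rate"]], x$removed[["maf"]], x$removed[["hwe"]]))
  invisible(x)
}

#' Method-of-moments identity-by-descent estimate (PI_HAT)
#'
#' PLINK-convention estimator: observed identity-by-state counts are combined
#' with their expectations given the allele frequencies to solve for
#' P(IBD = 0, 1, 2); `PI_HAT = P(IBD=1)/2 + P(IBD=2)`, clamped to `[0, 1]`.
#' Pairwise-missing genotypes are dropped.
#'
#' @param g1,g2 dosage vectors (0/1/2, NA allowed) of equal length.
#' @param allele_freqs ALT allele frequencies per variant; estimated from the
#'   two samples' cohort if omitted (supply cohort frequencies in practice).
#' @return PI_HAT in `[0, 1]`.
#' @export
ibd_pi_hat <- function(g1, g2, allele_freqs) {
  stopifnot(length(g1) == length(g2),
            length(allele_freqs) == length(g1))
  ok <- !is.na(g1) & !is.na(g2) & allele_freqs > 0 & allele_freqs < 1
  if (sum(ok) < 100)
    stop_semscan("fewer than 100 informative variants for IBD",
                 "semscan_insufficient_data")
  g1 <- g1[ok]; g2 <- g2[ok]; p <- allele_freqs[ok]; q <- 1 - p
  ibs <- 2 - abs(g1 - g2)
  I0 <- sum(ibs == 0); I1 <- sum(ibs == 1); I2 <- sum(ibs == 2)
  # expected IBS-class probabilities given IBD state (HWE, random mating)
  e0_z0 <- sum(2 * p^2 * q^2)
  e1_z0 <- sum(4 * p^3 * q + 4 * p * q^3)
  e2_z0 <- sum(p^4 + q^4 + 4 * p^2 * q^2)
  e1_z1 <- sum(2 * p^2 * q + 2 * p * q^2)
  e2_z1 <- sum(p^3 + q^3 + p^2 * q + p * q^2)
  z0 <- I0 / e0_z0
  z1 <- (I1 - z0 * e1_z0) / e1_z1
  z2 <- (I2 - z0 * e2_z0 - z1 * e2_z1) / length(g1)
  z <- pmax(c(z0, z1, z2), 0)
  z <- z / sum(z)
  min(max(z[2] / 2 + z[3], 0), 1)
}

#' Projection PCA for population stratification
#'
#' Variants are standardized by the reference panel's allele frequencies
#' (`(g - 2p) / sqrt(2 p (1-p))`); principal axes come from the reference
#' panel only and study samples are projected onto them.
#'
#' @param reference,study dosage matrices (samples x variants) over the same
#'   variant columns.
#' @param n_components number of components to return.
#' @return list with `ref_scores`, `study_scores`, `eigenvalues` (all reference
#'   eigenvalues, for scree inspection) and `freqs`.
#' @export
pca_stratify <- function(reference, study, n_components = 2L) {
  if (ncol(reference) == 0 || ncol(reference) != ncol(study))
    stop_semscan("reference and study must share a non-empty variant set",
                 "semscan_input_error")
  stopifnot(n_components >= 1)
  p <- colMeans(reference, na.rm = TRUE) / 2
  keep <- p > 0 & p < 1
  if (!any(keep))
    stop_semscan("no polymorphic shared variants", "semscan_input_error")
  p <- p[keep]
  sdv <- sqrt(2 * p * (1 - p))
  std <- function(M) {
    Z <- sweep(M[, keep, drop = FALSE], 2, 2 * p, "-")
    Z <- sweep(Z, 2, sdv, "/")
    Z[is.na(Z)] <- 0
    Z
  }
  Zr <- std(reference)
  sv <- svd(Zr, nu = 0)
  eigenvalues <- sv$d^2 / (nrow(Zr) - 1)
  k <- min(n_components, ncol(sv$v))
  rot <- sv$v[, seq_len(k), drop = FALSE]
  list(ref_scores = Zr %*% rot,
       study_scores = std(study) %*% rot,
       eigenvalues = eigenvalues,
       freqs = p)
}

#' Flag stratification outliers by distance from the reference centroid
#'
#' Generalizes visual cluster exclusion to a radius rule: a study sample is an
#' outlier if it lies beyond `k` pooled reference standard deviations from the
#' reference centroid in PC space.
#'
#' @param pca result of [pca_stratify()].
#' @param k radius in reference SD units (default 6).
#' @return logical vector over study samples, TRUE = outlier.
#' @export
pca_outliers <- function(pca, k = 6) {
  ctr <- colMeans(pca$ref_scores)
  sds <- apply(pca$ref_scores, 2, sd)
  d2 <- sweep(pca$study_scores, 2, ctr, "-")
  d2 <- sweep(d2, 2, pmax(sds, 1e-12), "/")
  sqrt(rowSums(d2^2)) > k
}
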