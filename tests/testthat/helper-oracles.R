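# Independent oracles and small data builders shared across tests.

# Hardy-Weinberg exact p by direct enumeration of the conditional distribution
# over heterozygote counts (log-multinomial form, no recurrence).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nr <- 2 * min(n_AA, n_aa) + n_Aa
  hets <- seq(nr %% 2, min(nr, 2 * n - nr), by = 2)
  lp <- vapply(hets, function(h) {
    r <- (nr - h) / 2
    c <- (2 * n - nr - h) / 2
    lgamma(n + 1) - lgamma(r + 1) - lgamma(h + 1) - lgamma(c + 1) + h * log(2)
  }, 0)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hets)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

# data matrix whose sample covariance equals S exactly: whiten a random matrix
# to identity covariance, then colour by chol(S)
exact_cov_data <- function(n, S, seed = 1) {
  set.seed(seed)
  p <- ncol(S)
  Z <- matrix(rnorm(n * p), n, p)
  Z <- scale(Z, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))
  X <- Z %*% chol(S)
  colnames(X) <- colnames(S)
  X
}

# draws from the one-factor model with standardized indicators
sim_factor_data <- function(n, loadings) {
  f <- rnorm(n)
  Y <- outer(f, loadings) +
    matrix(rnorm(n * length(loadings)), n) %*%
    diag(sqrt(1 - loadings^2), length(loadings))
  colnames(Y) <- paste0("y", seq_along(loadings))
  Y
}

PAPER_LOADINGS <- c(0.842, 0.657, 0.787, 0.823)

# per-observation negative loglik of the latent-regression model, written
# directly from the multivariate-normal density (independent of the package's
# moment-based code path); used with generic optimizers as an ML oracle
naive_latreg_nll <- function(th, Y, W) {
  p <- ncol(Y); q <- ncol(W)
  nu <- th[1:p]; g <- th[(p + 1):(2 * p)]; d <- th[(2 * p + 1):(3 * p)]
  b <- th[(3 * p + 1):(3 * p + q)]
  if (any(d <= 1e-8)) return(1e10)
  Sig <- tcrossprod(g) + diag(d)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  E <- Y - sweep(outer(as.numeric(W %*% b), g), 2, nu, "+")
  Q <- forwardsolve(t(ch), t(E))
  0.5 * (nrow(Y) * (p * log(2 * pi) + 2 * sum(log(diag(ch)))) + sum(Q^2))
}

# small genotype dataset wrapper for hand-built dosage matrices
toy_geno <- function(dosage, pos = NULL, chrom = "1") {
  m <- ncol(dosage)
  ids <- sprintf("v%03d", seq_len(m))
  colnames(dosage) <- ids
  af <- colMeans(dosage, na.rm = TRUE) / 2
  structure(list(
    dosage = dosage,
    variants = data.frame(chrom = chrom,
                          pos = pos %||% (seq_len(m) * 1000L),
                          id = ids, ref = "A", alt = "G",
                          maf = pmin(af, 1 - af), block = 1L,
                          stringsAsFactors = FALSE),
    samples = data.frame(id = sprintf("S%03d", seq_len(nrow(dosage))),
                         stringsAsFactors = FALSE)),
    class = "geno_ds")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
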