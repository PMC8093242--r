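# Maximum-likelihood one-factor structural equation models.
#
# Measurement model: y_k = nu_k + gamma_k * F + eps_k, eps_k ~ N(0, delta_k),
# latent variance fixed to 1 for identification, so the implied covariance is
# Sigma = gamma gamma' + diag(delta).  The per-variant model adds exogenous
# predictors of the latent factor: F = b' w + zeta, Var(zeta) = 1, leaving the
# conditional covariance unchanged and moving the predictors into the mean,
# E[y | w] = nu + gamma (b' w).  Estimation is quasi-Newton (L-BFGS-B) on the
# exact likelihood with analytic gradients; all likelihood evaluations reduce
# to cross-product moments, so cost is independent of sample size inside the
# optimizer.

# ---- covariance-only machinery ------------------------------------------

# ML discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - p and gradient
.fml <- function(theta, S, p) {
  g <- theta[1:p]; d <- theta[(p + 1):(2 * p)]
  Sig <- tcrossprod(g) + diag(d, p)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, 2 * p)))
  iSig <- chol2inv(ch)
  ldet <- 2 * sum(log(diag(ch)))
  A <- iSig - iSig %*% S %*% iSig
  list(value = ldet + sum(iSig * S) - determinant(S)$modulus[1] - p,
       grad = c(2 * A %*% g, diag(A)))
}

.fit_cov_ml <- function(S, restarts = 5) {
  p <- ncol(S)
  R <- stats::cov2cor(S)
  e <- eigen(R, symmetric = TRUE)
  g0 <- e$vectors[, 1] * sqrt(max(e$values[1] - 1, 0.25))
  g0 <- pmin(pmax(abs(g0), 0.2), 0.95) * sign(g0 + (g0 == 0))
  g0 <- g0 * sqrt(diag(S))
  d0 <- pmax(diag(S) - g0^2, 0.05 * diag(S))
  start <- c(g0, d0)
  best <- NULL
  for (r in 0:restarts) {
    st <- if (r == 0) start else start * exp(0.2 * sin(seq_along(start) * (r + 0.7) * 1.3))
    opt <- optim(st, fn = function(th) .fml(th, S, p)$value,
                 gr = function(th) .fml(th, S, p)$grad,
                 method = "L-BFGS-B",
                 lower = c(rep(-Inf, p), rep(1e-6, p)),
                 control = list(maxit = 500, factr = 1e5, pgtol = 1e-10))
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
    if (best$convergence == 0) break
  }
  best
}

#' Upper-tail chi-square p-value
#'
#' @param statistic chi-square statistic (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return upper-tail probability of the central chi-square distribution.
#' @export
chi2_pvalue <- function(statistic, df) {
  stopifnot(statistic >= 0, df >= 1)
  pchisq(statistic, df, lower.tail = FALSE)
}

#' RMSEA with confidence interval
#'
#' Point estimate `sqrt(max(chisq - df, 0) / (df * (n_obs - 1)))`; interval
#' bounds by inverting the noncentral chi-square distribution at
#' `(1 +/- confidence)/2` and mapping the noncentrality through
#' `lambda -> sqrt(lambda / (df * (n_obs - 1)))`, lower bound clamped at 0.
#'
#' @param chi_square fit statistic.
#' @param df degrees of freedom.
#' @param n_obs number of observations.
#' @param confidence interval coverage (default 0.90, the SEM convention).
#' @return named numeric: estimate, lower, upper.
#' @export
rmsea_with_ci <- function(chi_square, df, n_obs, confidence = 0.90) {
  stopifnot(df >= 1, n_obs >= 2)
  scale <- df * (n_obs - 1)
  est <- sqrt(max(chi_square - df, 0) / scale)
  hi <- (1 + confidence) / 2
  lo <- (1 - confidence) / 2
  ncp_solve <- function(target) {
    # lambda with P(chisq_df(lambda) <= chi_square) = target
    f <- function(l) pchisq(chi_square, df, ncp = l) - target
    if (f(0) < 0) return(0)
    upper <- max(chi_square * 2, df * 4, 10)
    while (f(upper) > 0) upper <- upper * 2
    uniroot(f, c(0, upper), tol = 1e-10)$root
  }
  lower <- sqrt(ncp_solve(hi) / scale)
  upper <- sqrt(ncp_solve(lo) / scale)
  c(estimate = est, lower = lower, upper = upper)
}

# ---- mean-structure machinery (latent regressed on exogenous predictors) --

# negative loglik and gradient in moment form; theta = (nu_p, gamma_p,
# delta_p, b_q).  mom holds n, Syy, Sy1, SyW, SWW, SW1.
.nll_latreg <- function(theta, mom, p, q) {
  nu <- theta[1:p]; g <- theta[(p + 1):(2 * p)]
  d <- theta[(2 * p + 1):(3 * p)]
  b <- if (q > 0) theta[(3 * p + 1):(3 * p + q)] else numeric(0)
  n <- mom$n
  Sig <- tcrossprod(g) + diag(d, p)
  ch <- tryCatch(chol(Sig), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = rep(0, length(theta))))
  iSig <- chol2inv(ch)
  ldet <- 2 * sum(log(diag(ch)))
  if (q > 0) {
    St <- sum(mom$SW1 * b)               # sum t_i
    Stt <- as.numeric(crossprod(b, mom$SWW %*% b))
    Syt <- as.numeric(mom$SyW %*% b)     # sum y_i t_i
  } else {
    St <- 0; Stt <- 0; Syt <- numeric(p)
  }
  M <- mom$Syy - tcrossprod(nu, mom$Sy1) - tcrossprod(mom$Sy1, nu) +
    n * tcrossprod(nu) - tcrossprod(g, Syt) - tcrossprod(Syt, g) +
    St * (tcrossprod(nu, g) + tcrossprod(g, nu)) + Stt * tcrossprod(g)
  val <- n / 2 * (p * log(2 * pi) + ldet) + 0.5 * sum(iSig * M)
  A <- iSig - iSig %*% (M / n) %*% iSig
  g_nu <- as.numeric(iSig %*% (n * nu + St * g - mom$Sy1))
  g_g <- n * as.numeric(A %*% g) +
    as.numeric(iSig %*% (St * nu + Stt * g - Syt))
  g_d <- n / 2 * diag(A)
  grad <- c(g_nu, g_g, g_d)
  if (q > 0) {
    g_b <- -as.numeric(crossprod(mom$SyW, iSig %*% g)) +
      as.numeric(crossprod(nu, iSig %*% g)) * mom$SW1 +
      as.numeric(crossprod(g, iSig %*% g)) * as.numeric(mom$SWW %*% b)
    grad <- c(grad, g_b)
  }
  list(value = val, grad = grad)
}

.moments_latreg <- function(Y, W) {
  n <- nrow(Y)
  if (is.null(W)) {
    list(n = n, Syy = crossprod(Y), Sy1 = colSums(Y),
         SyW = NULL, SWW = NULL, SW1 = NULL)
  } else {
    list(n = n, Syy = crossprod(Y), Sy1 = colSums(Y),
         SyW = crossprod(Y, W), SWW = crossprod(W), SW1 = colSums(W))
  }
}

.fit_latreg <- function(Y, W, start = NULL, restarts = 5) {
  p <- ncol(Y); q <- if (is.null(W)) 0L else ncol(W)
  mom <- .moments_latreg(Y, W)
  if (is.null(start)) {
    cm <- .fit_cov_ml(cov(Y))
    start <- c(colMeans(Y), cm$par, rep(0, q))
  }
  lower <- c(rep(-Inf, p), rep(-Inf, p), rep(1e-6, p), rep(-Inf, q))
  best <- NULL
  for (r in 0:restarts) {
    st <- if (r == 0) start else start + 0.1 * sin(seq_along(start) * (r + 0.7) * 1.3)
    st <- pmax(st, lower + 1e-8)
    opt <- optim(st, fn = function(th) .nll_latreg(th, mom, p, q)$value,
                 gr = function(th) .nll_latreg(th, mom, p, q)$grad,
                 method = "L-BFGS-B", lower = lower,
                 control = list(maxit = 500, factr = 1e5, pgtol = 1e-10))
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
    if (best$convergence == 0) break
  }
  H <- optimHess(best$par, fn = function(th) .nll_latreg(th, mom, p, q)$value,
                 gr = function(th) .nll_latreg(th, mom, p, q)$grad)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, length(best$par),
                                                      length(best$par)))
  list(opt = best, vcov = vc, mom = mom, p = p, q = q,
       loglik = -best$value)
}

# saturated-model loglik: unrestricted multivariate regression of Y on [1, W]
.loglik_saturated <- function(Y, W) {
  n <- nrow(Y); p <- ncol(Y)
  X <- if (is.null(W)) matrix(1, n, 1) else cbind(1, W)
  B <- qr.coef(qr(X), Y)
  E <- Y - X %*% B
  Sres <- crossprod(E) / n
  -n / 2 * (p * log(2 * pi) + determinant(Sres)$modulus[1] + p)
}

# ---- user-facing fits -----------------------------------------------------

#' Fit the one-common-factor measurement model
#'
#' Maximum-likelihood confirmatory factor analysis with a single latent
#' variable behind the four symptom-category scores.  Identification fixes
#' the latent variance to 1; the factor sign is resolved so the first loading
#' is non-negative.  Without covariates the fit statistic is
#' `(N - 1) * F_ML` against the saturated covariance model (df = 2 for four
#' indicators); with covariates (exogenous predictors of the latent factor)
#' it is the likelihood-ratio statistic against the saturated multivariate
#' regression.
#'
#' @param data data frame or matrix of indicator columns (non-numeric columns
#'   such as `id` are dropped); complete cases are used.
#' @param covariates optional data frame/matrix of numeric covariates
#'   predicting the latent factor.
#' @param n_obs sample size used for fit statistics; defaults to the number of
#'   complete cases (recorded in the output so the choice is auditable).
#' @param confidence RMSEA interval coverage.
#' @return an object of class `one_factor_fit`.
#' @export
fit_one_factor <- function(data, covariates = NULL, n_obs = NULL,
                           confidence = 0.90) {
  Y <- as.matrix(data[, vapply(as.data.frame(data), is.numeric, TRUE),
                      drop = FALSE])
  W <- if (!is.null(covariates))
    as.matrix(covariates[, vapply(as.data.frame(covariates), is.numeric, TRUE),
                         drop = FALSE]) else NULL
  cc <- if (is.null(W)) complete.cases(Y) else complete.cases(Y, W)
  Y <- Y[cc, , drop = FALSE]
  if (!is.null(W)) W <- W[cc, , drop = FALSE]
  n <- nrow(Y); p <- ncol(Y)
  if (n < 50)
    stop_semscan("at least 50 complete cases are required", "semscan_input_error")
  n_obs <- n_obs %||% n
  if (is.null(W)) {
    S <- cov(Y)
    opt <- .fit_cov_ml(S)
    if (opt$convergence != 0)
      stop_semscan(sprintf("one-factor ML did not converge (code %d: %s)",
                           opt$convergence, opt$message),
                   "semscan_estimation_error")
    gam <- opt$par[1:p]; del <- opt$par[(p + 1):(2 * p)]
    if (gam[1] < 0) gam <- -gam
    chisq <- (n_obs - 1) * opt$value
    df <- p * (p + 1) / 2 - 2 * p
    # observed information of the loglik  l = -(n-1)/2 * F_ML
    H <- optimHess(c(gam, del), fn = function(th) .fml(th, S, p)$value,
                   gr = function(th) .fml(th, S, p)$grad)
    vc <- tryCatch(solve((n - 1) / 2 * H),
                   error = function(e) matrix(NA_real_, 2 * p, 2 * p))
    loglik <- .loglik_saturated(Y, NULL) - (n - 1) / 2 * opt$value
    nu <- colMeans(Y)
    cov_eff <- NULL; cov_se <- NULL
  } else {
    fit <- .fit_latreg(Y, W)
    if (fit$opt$convergence != 0)
      stop_semscan("one-factor ML did not converge", "semscan_estimation_error")
    th <- fit$opt$par
    nu <- th[1:p]; gam <- th[(p + 1):(2 * p)]; del <- th[(2 * p + 1):(3 * p)]
    cov_eff <- th[(3 * p + 1):(3 * p + fit$q)]
    sflip <- if (gam[1] < 0) -1 else 1
    gam <- sflip * gam; cov_eff <- sflip * cov_eff
    names(cov_eff) <- colnames(W)
    cov_se <- sqrt(diag(fit$vcov)[(3 * p + 1):(3 * p + fit$q)])
    loglik <- fit$loglik
    chisq <- max(2 * (.loglik_saturated(Y, W) - loglik), 0)
    df <- (p * (p + 1) / 2 + p * (1 + fit$q)) - (3 * p + fit$q)
    vc <- fit$vcov[c((p + 1):(3 * p)), c((p + 1):(3 * p)), drop = FALSE]
  }
  heywood <- any(del <= 2e-6)
  if (heywood)
    warning("Heywood case: residual variance at lower bound 1e-6")
  se <- sqrt(pmax(diag(vc)[1:p], 0))
  rmsea <- rmsea_with_ci(chisq, df, n_obs, confidence)
  cats <- colnames(Y) %||% paste0("y", 1:p)
  structure(list(loadings = setNames(gam, cats),
                 loading_se = setNames(se, cats),
                 residual_var = setNames(del, cats),
                 intercepts = setNames(nu, cats),
                 latent_var = 1,
                 covariate_effects = cov_eff,
                 covariate_se = cov_se,
                 chi_square = chisq, df = df,
                 p_value = chi2_pvalue(chisq, df),
                 rmsea = rmsea,
                 loglik = loglik,
                 n_obs = n_obs, n_used = n,
                 heywood = heywood,
                 vcov = vc,
                 confidence = confidence),
            class = "one_factor_fit")
}

#' Per-variant latent-mediated association model
#'
#' The SNP dosage and the covariates enter as exogenous predictors of the
#' latent factor; the measurement part is that of [fit_one_factor()].  The
#' reported `beta` is the path coefficient from dosage to the latent factor,
#' with a Wald test `p = 2 * pnorm(-|beta/se|)`.
#'
#' @param data indicator columns (as in [fit_one_factor()]).
#' @param dosage numeric dosage vector (one value per subject).
#' @param covariates optional numeric covariates.
#' @param start optional warm start: a `one_factor_fit` on the same data (the
#'   no-SNP model), or a raw parameter vector.
#' @return an object of class `variant_fit` with `beta`, `se`, `z`, `p`,
#'   loadings, residual variances, covariate effects and a convergence flag.
#' @export
fit_variant_model <- function(data, dosage, covariates = NULL, start = NULL) {
  Y <- as.matrix(data[, vapply(as.data.frame(data), is.numeric, TRUE),
                      drop = FALSE])
  if (length(dosage) != nrow(Y))
    stop_semscan("dosage length must equal the number of subjects",
                 "semscan_input_error")
  W <- cbind(dosage = dosage)
  if (!is.null(covariates)) {
    CV <- as.matrix(covariates[, vapply(as.data.frame(covariates), is.numeric,
                                        TRUE), drop = FALSE])
    W <- cbind(W, CV)
  }
  cc <- complete.cases(Y, W)
  Y <- Y[cc, , drop = FALSE]; W <- W[cc, , drop = FALSE]
  if (var(W[, 1]) == 0)
    stop_semscan("monomorphic variant: dosage has zero variance",
                 "semscan_monomorphic")
  p <- ncol(Y); q <- ncol(W)
  st <- NULL
  if (inherits(start, "one_factor_fit")) {
    st <- c(start$intercepts, start$loadings, start$residual_var,
            0, start$covariate_effects %||% rep(0, q - 1))
  } else if (is.numeric(start)) st <- start
  fit <- .fit_latreg(Y, W, start = st)
  th <- fit$opt$par
  gam <- th[(p + 1):(2 * p)]
  bcoef <- th[(3 * p + 1):(3 * p + q)]
  sflip <- if (gam[1] < 0) -1 else 1
  gam <- sflip * gam; bcoef <- sflip * bcoef
  se_all <- sqrt(pmax(diag(fit$vcov)[(3 * p + 1):(3 * p + q)], 0))
  converged <- fit$opt$convergence == 0 && all(is.finite(se_all))
  beta <- bcoef[1]; se <- se_all[1]
  z <- if (converged && se > 0) beta / se else NA_real_
  structure(list(beta = beta, se = se, z = z,
                 p = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
                 covariate_effects = setNames(bcoef[-1], colnames(W)[-1]),
                 covariate_se = se_all[-1],
                 loadings = setNames(gam, colnames(Y)),
                 residual_var = setNames(th[(2 * p + 1):(3 * p)], colnames(Y)),
                 intercepts = setNames(th[1:p], colnames(Y)),
                 loglik = fit$loglik, n_used = nrow(Y),
                 converged = converged),
            class = "variant_fit")
}

# ---- methods --------------------------------------------------------------

#' @export
print.one_factor_fit <- function(x, ...) {
  cat("One-factor SEM fit (latent variance fixed to 1),",
      x$n_used, "complete cases\n")
  print(round(rbind(loading = x$loadings, se = x$loading_se,
                    residual = x$residual_var), 3))
  cat(sprintf("chi-square %.2f on %d df (p = %.2g); RMSEA %.3f [%.3f, %.3f] (%.0f%% CI)\n",
              x$chi_square, x$df, x$p_value, x$rmsea["estimate"],
              x$rmsea["lower"], x$rmsea["upper"], 100 * x$confidence))
  invisible(x)
}

#' @export
summary.one_factor_fit <- function(object, ...) {
  z <- object$loadings / object$loading_se
  tab <- data.frame(loading = object$loadings, se = object$loading_se,
                    z = z, p = 2 * pnorm(-abs(z)),
                    residual_var = object$residual_var)
  out <- list(coefficients = tab, covariates = NULL, fit = object)
  if (!is.null(object$covariate_effects)) {
    zc <- object$covariate_effects / object$covariate_se
    out$covariates <- data.frame(effect = object$covariate_effects,
                                 se = object$covariate_se, z = zc,
                                 p = 2 * pnorm(-abs(zc)))
  }
  class(out) <- "summary.one_factor_fit"
  out
}

#' @export
print.summary.one_factor_fit <- function(x, ...) {
  cat("Measurement model:\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$covariates)) {
    cat("Latent-factor covariate effects:\n")
    print(round(x$covariates, 4))
  }
  f <- x$fit
  cat(sprintf("chi-square %.2f on %d df (p = %.2g); RMSEA %.3f; loglik %.2f; N = %d\n",
              f$chi_square, f$df, f$p_value, f$rmsea["estimate"], f$loglik,
              f$n_obs))
  invisible(x)
}

#' @export
coef.one_factor_fit <- function(object, ...) {
  c(setNames(object$loadings, paste0("loading.", names(object$loadings))),
    setNames(object$residual_var,
             paste0("residual.", names(object$residual_var))),
    if (!is.null(object$covariate_effects))
      setNames(object$covariate_effects,
               paste0("covariate.", names(object$covariate_effects))))
}

#' @export
logLik.one_factor_fit <- function(object, ...) {
  structure(object$loglik,
            df = length(object$loadings) * 3 +
              length(object$covariate_effects %||% numeric(0)),
            nobs = object$n_used, class = "logLik")
}

#' @export
vcov.one_factor_fit <- function(object, ...) object$vcov

#' Implied covariance of a one-factor fit
#' @param fit a `one_factor_fit`.
#' @return the model-implied indicator covariance matrix.
#' @export
implied_covariance <- function(fit) {
  tcrossprod(fit$loadings) + diag(fit$residual_var, length(fit$loadings))
}

#' @export
predict.one_factor_fit <- function(object, newdata, ...) {
  # regression-method factor scores: F_hat = gamma' Sigma^-1 (y - nu)
  Y <- as.matrix(newdata[, names(object$loadings), drop = FALSE])
  iSig <- solve(implied_covariance(object))
  as.numeric(sweep(Y, 2, object$intercepts) %*% (iSig %*% object$loadings))
}

#' @export
fitted.one_factor_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    stop_semscan("supply the indicator data via 'newdata' (not stored in the fit)",
                 "semscan_input_error")
  fs <- predict(object, newdata)
  sweep(outer(fs, object$loadings), 2, object$intercepts, "+")
}

#' @export
residuals.one_factor_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    stop_semscan("supply the indicator data via 'newdata' (not stored in the fit)",
                 "semscan_input_error")
  as.matrix(newdata[, names(object$loadings), drop = FALSE]) -
    fitted(object, newdata)
}

#' @export
simulate.one_factor_fit <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- n %||% object$n_used
  g <- object$loadings; d <- object$residual_var
  out <- lapply(seq_len(nsim), function(s) {
    f <- rnorm(n)
    Y <- outer(f, g) + matrix(rnorm(n * length(g)), n) %*%
      diag(sqrt(d), length(g))
    sweep(Y, 2, object$intercepts, "+")
  })
  if (nsim == 1) out[[1]] else out
}

#' @export
plot.one_factor_fit <- function(x, ...) {
  mids <- graphics::barplot(x$loadings, ylim = c(0, 1.05),
                            ylab = "standardized loading",
                            main = "One-factor measurement model", ...)
  graphics::arrows(mids, x$loadings - 2 * x$loading_se,
                   mids, pmin(x$loadings + 2 * x$loading_se, 1.04),
                   angle = 90, code = 3, length = 0.04)
  invisible(x)
}

#' @export
print.variant_fit <- function(x, ...) {
  cat(sprintf("Variant model: beta = %.4f (se %.4f), z = %.2f, p = %.3g%s\n",
              x$beta, x$se, x$z, x$p,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}
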