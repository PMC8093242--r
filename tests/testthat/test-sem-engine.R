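test_that("exact one-factor covariance is recovered to numerical precision", {
  gam <- c(0.8, 0.6, 0.7, 0.75)
  S <- tcrossprod(gam) + diag(1 - gam^2)
  colnames(S) <- rownames(S) <- paste0("y", 1:4)
  X <- exact_cov_data(300, S, seed = 41)
  fit <- fit_one_factor(X)
  expect_equal(unname(fit$loadings), gam, tolerance = 1e-5)
  expect_equal(unname(fit$residual_var), 1 - gam^2, tolerance = 1e-5)
  expect_lt(fit$chi_square, 1e-6)
  expect_equal(fit$df, 2)
})

test_that("chi-square p-values match closed forms and the printed study fit", {
  expect_equal(signif(chi2_pvalue(22.5, 9), 2), 7.4e-3)
  expect_equal(chi2_pvalue(0, 5), 1.0)
  expect_equal(chi2_pvalue(3.841, 1), 0.050, tolerance = 1e-3)
})

test_that("RMSEA matches the printed study value and closed forms", {
  r <- rmsea_with_ci(22.5, 9, 1966)
  expect_equal(round(unname(r["estimate"]), 3), 0.028)
  expect_equal(unname(rmsea_with_ci(5, 9, 500)["estimate"]), 0)
  expect_equal(unname(rmsea_with_ci(18, 9, 1000)["estimate"]),
               sqrt(9 / (9 * 999)), tolerance = 1e-12)
  # interval is ordered and the lower bound clamps at zero for good fits
  expect_true(r["lower"] <= r["estimate"] && r["estimate"] <= r["upper"])
  expect_equal(unname(rmsea_with_ci(2, 9, 1000)["lower"]), 0)
})

test_that("simulated data at the study loadings are recovered within sampling error", {
  set.seed(42)
  Y <- sim_factor_data(1998, PAPER_LOADINGS)
  fit <- fit_one_factor(Y)
  expect_true(all(abs(fit$loadings - PAPER_LOADINGS) < 3 * fit$loading_se))
  expect_true(all(fit$loading_se > 0.01 & fit$loading_se < 0.04))
  expect_gt(fit$p_value, 1e-4)  # correctly specified model fits
})

test_that("independent indicators give near-zero loadings", {
  set.seed(43)
  Y <- matrix(rnorm(3000 * 4), 3000, 4)
  fit <- fit_one_factor(Y)
  # implied inter-indicator correlations gamma_i * gamma_j vanish; individual
  # loadings only shrink at the sqrt(sampling-error) rate
  prods <- tcrossprod(fit$loadings)
  expect_lt(max(abs(prods[upper.tri(prods)])), 0.05)
})

test_that("the factor sign convention puts the first loading non-negative", {
  set.seed(44)
  Y <- sim_factor_data(600, c(0.8, 0.7, 0.6, 0.75))
  Y[, 1] <- -Y[, 1]   # flip one indicator; gamma_1 would come out negative
  fit <- fit_one_factor(Y)
  expect_gte(fit$loadings[1], 0)
})

test_that("loadings and residuals are scale-equivariant", {
  set.seed(45)
  Y <- sim_factor_data(1200, c(0.8, 0.65, 0.7, 0.75))
  f1 <- fit_one_factor(Y)
  Y2 <- Y; Y2[, 2] <- 3 * Y2[, 2]
  f2 <- fit_one_factor(Y2)
  expect_equal(unname(f2$loadings[2]), unname(3 * f1$loadings[2]),
               tolerance = 1e-5)
  expect_equal(unname(f2$residual_var[2]), unname(9 * f1$residual_var[2]),
               tolerance = 1e-4)
  expect_equal(f2$chi_square, f1$chi_square, tolerance = 1e-5)
})

test_that("variant model is null-calibrated for an unassociated dosage", {
  set.seed(46)
  n <- 400
  Y <- sim_factor_data(n, PAPER_LOADINGS)
  base <- fit_one_factor(Y)
  ps <- replicate(150, {
    g <- rbinom(n, 2, 0.3)
    fit_variant_model(Y, g, start = base)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_gt(min(ps), 1e-5)
})

test_that("variant model errors on monomorphic dosage and validates lengths", {
  Y <- sim_factor_data(100, PAPER_LOADINGS)
  expect_error(fit_variant_model(Y, rep(1, 100)),
               class = "semscan_monomorphic")
  expect_error(fit_variant_model(Y, rep(0:1, 10)), class = "semscan_input_error")
})

test_that("ML solution matches a generic multi-start optimizer on a small instance", {
  set.seed(47)
  n <- 200
  g <- rbinom(n, 2, 0.4)
  covar <- rnorm(n)
  lat <- 0.3 * as.numeric(scale(g)) + rnorm(n)
  Y <- outer(lat, PAPER_LOADINGS) +
    matrix(rnorm(n * 4), n) %*% diag(sqrt(1 - PAPER_LOADINGS^2))
  colnames(Y) <- paste0("y", 1:4)
  vf <- fit_variant_model(Y, g, data.frame(c1 = covar))
  W <- cbind(g, covar)
  best <- Inf
  for (s in 1:12) {
    set.seed(400 + s)
    st <- c(colMeans(Y), runif(4, 0.2, 1), runif(4, 0.3, 1), rnorm(2, 0, 0.2))
    o <- optim(st, naive_latreg_nll, Y = Y, W = W, method = "Nelder-Mead",
               control = list(maxit = 1000))
    o <- optim(o$par, naive_latreg_nll, Y = Y, W = W, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(vf$loglik, -best, tolerance = 1e-4)
})

test_that("vanishing residuals reduce the latent path to a linear regression", {
  set.seed(48)
  n <- 800
  g <- rbinom(n, 2, 0.3)
  lat <- 0.25 * (g - mean(g)) + rnorm(n)
  eps <- 0.02
  gam <- c(0.9, 0.8, 0.85, 0.88)
  Y <- outer(lat, gam) + eps * matrix(rnorm(n * 4), n)
  vf <- fit_variant_model(Y, g)
  # with near-zero residuals the common component is observed directly and
  # beta equals its regression on dosage
  common <- as.numeric(Y %*% gam / sum(gam^2))
  beta_lm <- unname(coef(lm(common ~ g))[2])
  expect_equal(vf$beta, beta_lm, tolerance = 0.1)
})

test_that("fit object methods are coherent", {
  set.seed(49)
  Y <- sim_factor_data(500, c(0.8, 0.7, 0.75, 0.65))
  fit <- fit_one_factor(Y)
  expect_output(print(fit), "One-factor SEM fit")
  expect_output(print(summary(fit)), "Measurement model")
  expect_length(coef(fit), 8)
  expect_equal(attr(logLik(fit), "nobs"), 500)
  fs <- predict(fit, Y)
  expect_length(fs, 500)
  expect_gt(cor(fs, Y %*% fit$loadings), 0.99)
  res <- residuals(fit, newdata = Y)
  expect_equal(dim(res), dim(Y))
  sim <- simulate(fit, seed = 1, n = 200)
  expect_equal(dim(sim), c(200, 4))
  # implied covariance close to the sample covariance of a big simulation
  big <- simulate(fit, seed = 2, n = 20000)
  expect_equal(cov(big), implied_covariance(fit), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("one-factor fit with covariates reports the extended model df", {
  set.seed(50)
  n <- 700
  covs <- data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  lat <- 0.2 * covs$age + rnorm(n)
  Y <- outer(lat, PAPER_LOADINGS) +
    matrix(rnorm(n * 4), n) %*% diag(sqrt(1 - PAPER_LOADINGS^2))
  fit <- fit_one_factor(Y, covariates = covs)
  expect_equal(fit$df, 8)  # 2 + 3q for q = 2
  expect_lt(abs(fit$covariate_effects["age"] - 0.2), 0.12)  # ~3 SE at n=700
  expect_gt(fit$p_value, 1e-4)
})
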