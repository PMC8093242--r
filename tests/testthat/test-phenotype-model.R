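make_quest <- function(before, after) {
  items <- names(default_item_map())
  df <- data.frame(id = sprintf("S%02d", seq_len(nrow(before))))
  for (j in seq_along(items)) df[[paste0(items[j], "_before")]] <- before[, j]
  for (j in seq_along(items)) df[[paste0(items[j], "_after")]] <- after[, j]
  df
}

test_that("delta scores are after minus before with validation", {
  before <- matrix(2L, 3, 14); after <- matrix(5L, 3, 14)
  d <- delta_scores(make_quest(before, after))
  expect_true(all(as.matrix(d[, -1]) == 3))
  d0 <- delta_scores(make_quest(after, after))
  expect_true(all(as.matrix(d0[, -1]) == 0))
  bad <- make_quest(before, after)
  bad$q3_after[2] <- 9L
  err <- tryCatch(delta_scores(bad), error = identity)
  expect_s3_class(err, "semscan_validation_error")
  expect_match(conditionMessage(err), "S02")
  expect_match(conditionMessage(err), "q3")
})

test_that("delta means are linear: mean delta equals mean after minus mean before", {
  set.seed(31)
  before <- matrix(sample(1:4, 50 * 14, TRUE), 50)
  after <- matrix(sample(3:7, 50 * 14, TRUE), 50)
  d <- as.matrix(delta_scores(make_quest(before, after))[, -1])
  expect_equal(mean(d), mean(after) - mean(before))
  # the study-scale sanity check: before 2.05, after 4.70 -> delta 2.65
  expect_equal(4.70 - 2.05, 2.65)
})

test_that("category scores are the member-item means", {
  before <- matrix(1L, 2, 14)
  after <- matrix(1L, 2, 14)
  after[1, 1:3] <- c(3L, 5L, 7L)   # q1..q3 deltas 2, 4, 6
  after[1, 8:9] <- c(2L, 6L)       # q8, q9 deltas 1, 5
  cs <- category_scores(delta_scores(make_quest(before, after)))
  expect_equal(cs$asthenopic[1], 4.0)
  expect_equal(cs$visual[1], 3.0)
  expect_true(all(as.matrix(cs[2, -1]) == 0))
  # all items equal c -> every category equals c
  after2 <- matrix(4L, 2, 14)
  cs2 <- category_scores(delta_scores(make_quest(before, after2)))
  expect_true(all(as.matrix(cs2[, -1]) == 3))
  expect_error(category_scores(data.frame(q1 = 1)),
               class = "semscan_validation_error")
})

test_that("equicorrelated triple has partial correlations of exactly 1/3", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  X <- exact_cov_data(200, R, seed = 32)
  P <- partial_correlation_matrix(X)
  expect_equal(P[upper.tri(P)], rep(1 / 3, 3), tolerance = 1e-10)
})

test_that("partial correlations match the regression-residual oracle", {
  set.seed(33)
  for (rep in 1:5) {
    X <- matrix(rnorm(150 * 6), 150) %*% matrix(rnorm(36), 6)
    P <- partial_correlation_matrix(X)
    for (i in 1:2) for (j in (i + 1):4) {
      o <- setdiff(seq_len(6), c(i, j))
      ri <- lm.fit(cbind(1, X[, o]), X[, i])$residuals
      rj <- lm.fit(cbind(1, X[, o]), X[, j])$residuals
      expect_equal(P[i, j], cor(ri, rj), tolerance = 1e-10)
    }
  }
})

test_that("independent variables give near-zero partial correlations", {
  set.seed(34)
  X <- matrix(rnorm(4000 * 5), 4000)
  P <- partial_correlation_matrix(X)
  expect_lt(max(abs(P[upper.tri(P)])), 0.06)
})

test_that("a one-factor model with positive loadings yields all-positive partials", {
  set.seed(35)
  Y <- sim_factor_data(5000, c(0.8, 0.7, 0.75, 0.85, 0.6, 0.7))
  P <- partial_correlation_matrix(Y)
  expect_true(all(P[upper.tri(P)] > 0))
})

test_that("unconstrained GGM fit reproduces the inverse sample covariance", {
  set.seed(36)
  S <- cov(matrix(rnorm(200 * 5), 200))
  fit <- semscan:::ggm_fit(S, matrix(1, 5, 5) - diag(5))
  expect_equal(fit$K, solve(S), tolerance = 1e-7)
})

test_that("covariance selection honours the AIC bookkeeping invariants", {
  set.seed(37)
  Ktrue <- diag(5); for (i in 1:4) Ktrue[i, i + 1] <- Ktrue[i + 1, i] <- -0.4
  X <- matrix(rnorm(3000 * 5), 3000) %*% chol(solve(Ktrue))
  cs <- covariance_selection(cov(X), 3000)
  expect_true(all(diff(cs$aic_trace) < 0))
  expect_equal(length(cs$aic_trace), nrow(cs$removed %||% matrix(0, 0, 2)) + 1)
  expect_true(isSymmetric(cs$adjacency))
  expect_true(all(diag(cs$adjacency) == 0))
  expect_true(all(abs(cs$pcor) <= 1 + 1e-12))
  # zero-constrained entries of the fitted precision really are zero
  expect_true(all(abs(cs$precision[cs$adjacency == 0 &
                                     diag(5) == 0]) < 1e-6))
})

test_that("covariance selection keeps strong true edges and prunes null edges", {
  set.seed(38)
  Ktrue <- diag(5); for (i in 1:4) Ktrue[i, i + 1] <- Ktrue[i + 1, i] <- -0.4
  L <- chol(solve(Ktrue))
  chain <- cbind(1:4, 2:5)
  kept_true <- 0; null_edges <- 0
  for (r in 1:15) {
    X <- matrix(rnorm(5000 * 5), 5000) %*% L
    cs <- covariance_selection(cov(X), 5000)
    kept_true <- kept_true + all(cs$adjacency[chain] == 1)
    null <- sum(cs$adjacency[upper.tri(cs$adjacency)]) - sum(cs$adjacency[chain] == 1)
    null_edges <- null_edges + null
  }
  expect_equal(kept_true, 15)          # strong edges never dropped
  # AIC retains each of the 6 null edges w.p. P(chi2_1 > 2) ~ 0.157
  expect_lt(null_edges / (15 * 6), 0.45)
})

test_that("saturated truth with strong partials removes no edges", {
  Ks <- matrix(-0.5, 4, 4); diag(Ks) <- 2.5
  S <- solve(Ks)
  cs <- covariance_selection(S, 10000)
  expect_equal(length(cs$aic_trace), 1)
  expect_equal(sum(cs$adjacency[upper.tri(cs$adjacency)]), 6)
})

test_that("item PCA handles identity, rank-1 and one-factor structures", {
  p14 <- diag(14)
  r <- item_pca(p14)
  expect_equal(r$eigenvalues, rep(1, 14))
  expect_equal(r$variance_share, rep(1 / 14, 14))
  v <- seq(0.3, 0.9, length.out = 6)
  r1 <- item_pca(tcrossprod(v))
  expect_equal(r1$variance_share[1], 1, tolerance = 1e-12)
  set.seed(39)
  Y <- sim_factor_data(3000, rep(0.75, 8))
  rp <- item_pca(partial_correlation_matrix(Y))
  expect_true(all(rp$coordinates[, 1] > 0) || all(rp$coordinates[, 1] < 0))
  expect_error(item_pca(matrix(c(1, 2, 0, 1), 2)), class = "semscan_input_error")
})

test_that("clique diagnostic finds planted dense subnetworks", {
  set.seed(40)
  K <- diag(6)
  K[1:3, 1:3] <- -0.45; diag(K) <- 2
  X <- matrix(rnorm(4000 * 6), 4000) %*% chol(solve(K))
  cs <- covariance_selection(cov(X), 4000)
  cl <- find_cliques(cs, threshold = 0.1, min_size = 3)
  expect_true(any(vapply(cl, function(x) all(1:3 %in% x), TRUE)))
})
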