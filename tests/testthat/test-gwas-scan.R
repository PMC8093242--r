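fake_table <- function(z, chrom = "1") {
  n <- length(z)
  tab <- data.frame(chrom = chrom, pos = seq_len(n) * 1000L,
                    id = sprintf("v%04d", seq_len(n)), ref = "A", alt = "G",
                    maf = 0.3, n = 500L, beta = z * 0.05, se = 0.05, z = z,
                    p_raw = 2 * pnorm(-abs(z)), p_gc = 2 * pnorm(-abs(z)),
                    stringsAsFactors = FALSE)
  class(tab) <- c("assoc_table", "data.frame")
  tab
}

test_that("lambda_GC is 1 when every z^2 equals the chi-square median", {
  z <- rep(sqrt(0.4549364), 200)
  tab <- genomic_control(fake_table(z))
  expect_equal(attr(tab, "lambda_gc"), 1.0, tolerance = 1e-12)
  expect_equal(tab$p_gc, tab$p_raw)
})

test_that("doubling every z^2 doubles lambda and leaves adjusted p invariant", {
  set.seed(61)
  z <- rnorm(500, sd = 1.4)
  t1 <- genomic_control(fake_table(z))
  t2 <- genomic_control(fake_table(sqrt(2) * z))
  expect_equal(attr(t2, "lambda_gc"), 2 * attr(t1, "lambda_gc"),
               tolerance = 1e-12)
  expect_equal(t2$p_gc, t1$p_gc, tolerance = 1e-12)
})

test_that("standard-normal statistics give lambda near 1 and p_gc = p_raw when deflated", {
  set.seed(62)
  tab <- genomic_control(fake_table(rnorm(10000)))
  expect_gt(attr(tab, "lambda_gc"), 0.95)
  expect_lt(attr(tab, "lambda_gc"), 1.05)
  z_defl <- rnorm(1000, sd = 0.8)
  t2 <- genomic_control(fake_table(z_defl))
  expect_lt(attr(t2, "lambda_gc"), 1)
  expect_equal(t2$p_gc, t2$p_raw)
  expect_error(genomic_control(fake_table(rnorm(50))),
               class = "semscan_insufficient_data")
})

test_that("LD r2 handles identity, complement and independence", {
  set.seed(63)
  g1 <- rbinom(5000, 2, 0.3)
  expect_equal(ld_r2(g1, g1), 1.0)
  expect_equal(ld_r2(g1, 2L - g1), 1.0)
  g2 <- rbinom(5000, 2, 0.3)
  expect_lt(ld_r2(g1, g2), 0.01)
  expect_error(ld_r2(g1, rep(1L, 5000)), class = "semscan_undefined_ld")
  expect_error(ld_r2(g1[1], g2[1]), class = "semscan_insufficient_data")
})

test_that("locus definition spans correlated blocks and collapses leads greedily", {
  set.seed(64)
  n <- 800
  base <- rbinom(n, 2, 0.4)
  block <- sapply(1:5, function(i) {  # five nearly identical variants
    flip <- rbinom(n, 1, 0.02)
    pmin(pmax(base + flip * sample(c(-1L, 1L), n, TRUE), 0L), 2L)
  })
  iso <- rbinom(n, 2, 0.3)
  indep <- sapply(1:4, function(i) rbinom(n, 2, 0.3))
  dos <- cbind(block, iso, indep)
  panel <- toy_geno(dos, pos = c(1000L, 2000L, 3000L, 4000L, 5000L,
                                 500000L, 900000L, 901000L, 902000L, 903000L))
  z <- c(5.5, 5.8, 5.2, 5.4, 5.6, 5.0, 0.5, 0.1, -0.3, 0.2)
  tab <- fake_table(z)
  tab$pos <- panel$variants$pos
  tab$id <- panel$variants$id
  loci <- define_loci(tab, panel, p_threshold = 1e-5)
  expect_equal(nrow(loci), 2)
  blk <- loci[loci$lead_id == "v002", ]
  expect_equal(blk$start, 1000L)   # correlated block spans min..max member pos
  expect_equal(blk$end, 5000L)
  expect_equal(blk$n_members, 5L)
  iso_locus <- loci[loci$lead_id == "v006", ]
  expect_equal(iso_locus$start, iso_locus$end)  # single-position locus
  # no variant below threshold -> empty list
  expect_equal(nrow(define_loci(fake_table(rnorm(20)), panel)), 0)
})

test_that("scan on a causal variant puts the minimum p at that variant deterministically", {
  cfg <- sim_config(n_samples = 500, n_variants = 60, ld_block_size = 10,
                    ld_rho = 0.6,
                    causal_variants = data.frame(index = 25, beta = 0.5),
                    seed = 65)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  cats <- category_scores(delta_scores(ph$questionnaire))
  covs <- ph$covariates[, c("age", "sex")]
  tab <- run_scan(g, cats[, -1], covs, gc = FALSE)
  expect_equal(tab$id[which.min(tab$p_raw)], "var00025")
  expect_true(!is.unsorted(tab$pos))
  tab2 <- run_scan(g, cats[, -1], covs, gc = FALSE)
  expect_identical(tab, tab2)   # byte-identical rerun
})

test_that("single-trait scan detects a planted single-category effect", {
  set.seed(66)
  n <- 600
  g_causal <- rbinom(n, 2, 0.4)
  dos <- cbind(g_causal, rbinom(n, 2, 0.3), rbinom(n, 2, 0.2))
  geno <- toy_geno(dos)
  trait <- 0.4 * g_causal + rnorm(n)
  tab <- single_trait_scan(geno, trait, gc = FALSE)
  expect_equal(which.min(tab$p_raw), 1L)
  expect_lt(tab$p_raw[1], 1e-6)
  # exact linear function of dosage -> essentially perfect fit
  tab2 <- single_trait_scan(geno, 2 * g_causal + 1, gc = FALSE)
  expect_lt(tab2$p_raw[1], 1e-200)
})

test_that("multi-trait scan is more powerful than univariate scans at the causal variant", {
  # a latent effect spread over all four categories: the joint SEM statistic
  # should dominate each individual category's regression statistic
  set.seed(67)
  n <- 500
  reps <- 30
  z_multi <- numeric(reps)
  z_single <- matrix(0, reps, 4)
  for (r in 1:reps) {
    g <- rbinom(n, 2, 0.3)
    lat <- 0.28 * (g - mean(g)) + rnorm(n)
    Y <- outer(lat, PAPER_LOADINGS) +
      matrix(rnorm(n * 4), n) %*% diag(sqrt(1 - PAPER_LOADINGS^2))
    colnames(Y) <- paste0("y", 1:4)
    z_multi[r] <- abs(fit_variant_model(Y, g)$z)
    z_single[r, ] <- sapply(1:4, function(k)
      abs(summary(lm(Y[, k] ~ g))$coefficients["g", "t value"]))
  }
  # on average the joint test beats every univariate test
  for (k in 1:4) expect_gt(mean(z_multi), mean(z_single[, k]))
  # and per replicate it beats the median univariate statistic almost always
  expect_gte(mean(z_multi >= apply(z_single, 1, median)), 0.70)
})

test_that("plot-data exports carry both significance thresholds", {
  set.seed(68)
  tab <- fake_table(rnorm(100))
  dir <- tempfile("plots")
  paths <- export_plots_data(tab, dir)
  expect_true(all(file.exists(paths)))
  meta <- jsonlite::read_json(paths[["metadata"]])
  expect_equal(meta$genome_wide_threshold, 5.0e-8)
  expect_equal(meta$suggestive_threshold, 1.0e-5)
  qq <- read.table(paths[["qq"]], header = TRUE, sep = "\t")
  expect_equal(nrow(qq), 100)
  # uniform p-values stay near the diagonal
  expect_lt(max(abs(qq$expected - qq$observed)[qq$expected < 1]), 0.6)
  # single-row table exports one row
  p1 <- export_plots_data(fake_table(2), tempfile("p1"))
  expect_equal(nrow(read.table(p1[["manhattan"]], header = TRUE)), 1)
  pdf(NULL)
  expect_silent(plot_manhattan(tab))
  expect_silent(plot_qq(tab))
  dev.off()
})
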