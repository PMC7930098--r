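test_that("fit_trc matches the closed-form OLS oracle", {
  # perfect fit
  x <- rep(c(0, 0.5, 1), length.out = 10)
  fit <- fit_trc(0.3 * x, x)
  expect_equal(fit$beta, 0.3, tolerance = 1e-12)
  expect_lt(fit$se, 1e-8)

  # monomorphic variant
  expect_true(is.na(fit_trc(rnorm(10), rep(0.5, 10))$beta))

  # random instances against the oracle
  set.seed(21)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    x <- sample(c(0, 0.5, 1), n, replace = TRUE)
    if (var(x) == 0) x[1] <- 1 - x[1]
    y <- 0.2 * x + rnorm(n, 0, 0.5)
    fit <- fit_trc(y, x)
    o <- ols_oracle(y, x)
    expect_equal(fit$beta, o$beta, tolerance = 1e-12)
    expect_equal(fit$se, o$se, tolerance = 1e-12)
    expect_equal(fit$p, 2 * pt(-abs(o$beta / o$se), n - 2), tolerance = 1e-12)
  }
})

test_that("fit_trc recovers a simulated effect within 3 standard errors", {
  set.seed(99)
  hits <- sapply(1:50, function(i) {
    x <- sample(c(0, 0.5, 1), 100, replace = TRUE, prob = c(.49, .42, .09))
    y <- 0.2 * x + rnorm(100, 0, 0.5)
    f <- fit_trc(y, x)
    abs(f$beta - 0.2) < 3 * f$se
  })
  expect_gte(mean(hits), 0.9)
})

test_that("fit_asc matches the GLS oracle and handles degenerate input", {
  fit <- fit_asc(c(0.7, -0.7, 0.7), c(1, -1, 1), rep(1, 3))
  expect_equal(fit$beta, 0.7, tolerance = 1e-12)
  expect_lt(fit$se, 1e-8)

  expect_true(is.na(fit_asc(rnorm(5), rep(0, 5), rep(1, 5))$beta))

  set.seed(31)
  for (i in 1:100) {
    n <- 50
    x <- sample(c(-1, 0, 1), n, replace = TRUE)
    if (sum(x != 0) < 2) x[1:2] <- c(1, -1)
    w <- rexp(n) + 0.2
    y <- 0.4 * x + rnorm(n, 0, 1 / sqrt(w))
    fit <- fit_asc(y, x, w)
    o <- gls_oracle(y, x, w)
    expect_equal(fit$beta, o$beta, tolerance = 1e-10)
    expect_equal(fit$se, o$se, tolerance = 1e-10)
  }
})

test_that("meta_combine is the inverse-variance average with fallbacks", {
  m <- meta_combine(1, 1, 0, 1)
  expect_equal(m$beta, 0.5)
  expect_equal(m$se, 1 / sqrt(2), tolerance = 1e-9)

  # dominance limit: a huge second se returns component 1
  m2 <- meta_combine(0.3, 0.1, 5, 1e8)
  expect_equal(m2$beta, 0.3, tolerance = 1e-9)
  expect_equal(m2$se, 0.1, tolerance = 1e-9)

  # z = 1.959964 -> p ~ 0.05
  m3 <- meta_combine(1.959964, 1, NA, NA)
  expect_equal(m3$p, 0.05, tolerance = 1e-5)

  # symmetry and se shrinkage
  a <- meta_combine(0.2, 0.05, -0.1, 0.08)
  b <- meta_combine(-0.1, 0.08, 0.2, 0.05)
  expect_equal(a, b)
  expect_lte(a$se, min(0.05, 0.08))

  expect_true(is.na(meta_combine(NA, NA, NA, NA)$beta))
})

test_that("run_cis_scan falls back to trc and flags the method", {
  set.seed(5)
  n <- 60
  # no usable allele-specific reads at all
  cnt <- gene_counts(rpois(n, 800) + 10, rep(0, n), rep(0, n), rep(1e6, n))
  prep <- prepare_gene(cnt)
  geno <- toy_genotypes(n = n, pos = c(10L, 20L, 30L), seed = 2)
  res <- run_cis_scan(prep, geno)
  expect_equal(nrow(res), 3)
  expect_true(all(res$method == "trc"))
  expect_true(all(is.na(res$beta_asc)))
  expect_equal(res$beta_meta, res$beta_trc)
  expect_equal(res$se_meta, res$se_trc)
  # the combined p-value falls back to the normal-based component p
  expect_equal(res$p_meta, 2 * pnorm(-abs(res$beta_trc / res$se_trc)),
               tolerance = 1e-12)
})

test_that("flipping allele coding negates betas and keeps p-values", {
  sim <- simulate_dataset(sim_config(
    n_samples = 150, aFC = 1.5, n_variants = 3, n_causal = 1, seed = 8
  ))
  fc <- sim_filter_config()
  prep <- prepare_gene(sim$counts, fc)
  res <- run_cis_scan(prep, sim$geno, fc)
  flipped <- sim$geno
  flipped$hap1 <- 1 - flipped$hap1
  flipped$hap2 <- 1 - flipped$hap2
  res2 <- run_cis_scan(prep, flipped, fc)
  expect_equal(res2$beta_trc, -res$beta_trc, tolerance = 1e-9)
  expect_equal(res2$beta_asc, -res$beta_asc, tolerance = 1e-9)
  expect_equal(res2$p_meta, res$p_meta, tolerance = 1e-9)
})

test_that("permute_gene is deterministic and calibrated under permutation", {
  sim <- simulate_dataset(sim_config(n_samples = 40, aFC = 2, seed = 3))
  prep <- prepare_gene(sim$counts, sim_filter_config())
  p1 <- permute_gene(prep, seed = 77)
  p2 <- permute_gene(prep, seed = 77)
  expect_identical(p1$y_trc, p2$y_trc)
  expect_identical(p1$asc_mask, p2$asc_mask)
  expect_false(identical(p1$y_trc, prep$y_trc))
  # marginals preserved
  expect_equal(sort(p1$y_trc), sort(prep$y_trc))

  # n = 1 is the identity
  one <- prepare_gene(gene_counts(100, 0, 0, 1e6))
  expect_equal(permute_gene(one, 1)$y_trc, one$y_trc)

  # permuted strong-signal genes give uniform p-values
  fc <- sim_filter_config()
  pvals <- sapply(1:200, function(i) {
    s <- simulate_dataset(sim_config(
      n_samples = 100, aFC = 2, n_variants = 1, seed = 9000 + i
    ))
    pr <- permute_gene(prepare_gene(s$counts, fc), seed = i)
    run_cis_scan(pr, s$geno, fc)$p_meta[1]
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("mixqtl_scan runs the whole tabular pipeline over genes", {
  sim <- simulate_dataset(sim_config(n_samples = 120, aFC = 1.5,
                                     n_variants = 5, seed = 10))
  counts <- list(geneA = sim$counts)
  ann <- tibble::tibble(gene_id = "geneA", chrom = "1",
                        tss = sim$geno$variants$pos[3])
  res <- mixqtl_scan(sim$geno, counts, ann, cfg = sim_filter_config())
  expect_equal(unique(res$gene_id), "geneA")
  expect_equal(nrow(res), 5)
  expect_true(all(res$p_meta >= 0 & res$p_meta <= 1, na.rm = TRUE))
  # unknown gene is skipped quietly
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(gene_id = "nope", chrom = "1",
                                               tss = 1e5))
  expect_equal(nrow(mixqtl_scan(sim$geno, counts, ann2,
                                cfg = sim_filter_config())), 5)
})
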