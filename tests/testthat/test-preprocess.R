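test_that("compute_trc applies the log-abundance formula and zero imputation", {
  cnt <- gene_counts(
    total = c(200, 0, 2e6), asc1 = c(0, 0, 0), asc2 = c(0, 0, 0),
    libsize = c(1e6, 1e6, 1e6)
  )
  out <- compute_trc(cnt, filter_config())
  expect_equal(out$y_trc, c(log(1e-4), log(1 / 2e6), 0), tolerance = 1e-9)
  expect_equal(out$y_trc[1], -9.210340, tolerance = 1e-6)
  expect_equal(out$y_trc[2], -14.508658, tolerance = 1e-6)
  expect_true(all(out$trc_mask))
})

test_that("compute_asc computes log ratio, harmonic weight and masks", {
  cnt <- suppressWarnings(gene_counts(
    total = c(200, 300, 2000, 20),
    asc1 = c(50, 100, 1200, 10), asc2 = c(50, 50, 300, 10),
    libsize = rep(1e6, 4)
  ))
  out <- compute_asc(cnt, filter_config())
  expect_equal(out$y_asc[1], 0)
  expect_equal(out$raw_w[1], 25)
  expect_equal(out$y_asc[2], log(2), tolerance = 1e-9)
  expect_equal(out$raw_w[2], 1 / (0.01 + 0.02), tolerance = 1e-9)
  expect_false(out$asc_mask[3])  # outlier > 1000
  expect_false(out$asc_mask[4])  # <= 15 reads
})

test_that("allelic imbalance is antisymmetric in the two haplotypes", {
  set.seed(42)
  a1 <- rpois(50, 120) + 16
  a2 <- rpois(50, 80) + 16
  fwd <- compute_asc(suppressWarnings(gene_counts(a1 + a2, a1, a2, rep(1e6, 50))))
  rev <- compute_asc(suppressWarnings(gene_counts(a1 + a2, a2, a1, rep(1e6, 50))))
  expect_equal(fwd$y_asc, -rev$y_asc)
  expect_equal(fwd$raw_w, rev$raw_w)
})

test_that("cap_weights enforces the K-fold cap", {
  expect_equal(cap_weights(c(5, 100), n = 200), c(5, 50))
  # n = 50 -> K = 5
  expect_equal(cap_weights(c(2, 100), n = 50), c(2, 10))
  w <- rep(3.3, 4)
  expect_equal(cap_weights(w, n = 500), w)
  expect_length(cap_weights(numeric(0), n = 100), 0)
  # tiny n floors K at 1: all weights equalized
  expect_equal(cap_weights(c(1, 7), n = 5), c(1, 1))
  # property: ratio never exceeds K
  set.seed(7)
  for (n in c(30, 120, 800)) {
    rw <- rexp(40, 1 / 50) + 0.1
    w <- cap_weights(rw, n)
    expect_lte(max(w) / min(w), max(1, min(10, n / 10)) + 1e-12)
  }
})

test_that("gene-level asc filter counts qualifying samples at the boundary", {
  cfg <- filter_config()
  mk <- function(n_asc_ok, n_trc_ok, n = 600) {
    asc <- rep(0, n); asc[seq_len(n_asc_ok)] <- 50
    tot <- rep(0, n); tot[seq_len(n_trc_ok)] <- 100
    suppressWarnings(gene_counts(tot, asc, asc, rep(1e6, n)))
  }
  expect_true(gene_passes_asc_filters(mk(15, 500), cfg))
  expect_false(gene_passes_asc_filters(mk(14, 500), cfg))
  expect_false(gene_passes_asc_filters(mk(15, 499), cfg))
  zero <- filter_config(gene_min_asc_samples = 0, gene_asc_reads_per_hap = 0,
                        gene_min_trc_samples = 0, gene_trc_min_reads = 0)
  expect_true(gene_passes_asc_filters(mk(0, 0), zero))
})

test_that("covariate adjustment selects, residualizes and centers", {
  set.seed(11)
  n <- 500
  C <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("c1", "c2", "c3")))
  # no covariates (or none selected): output is the centered response
  y <- rnorm(n) + 5
  expect_equal(adjust_covariates(y, NULL), y - mean(y))

  # exact linear dependence: residuals ~ 0
  y2 <- 2 * C[, 1]
  out2 <- suppressWarnings(adjust_covariates(y2, C))
  expect_lt(max(abs(out2)), 1e-10)

  # Monte-Carlo: y = 0.5 c1 + noise; matches a direct two-stage OLS oracle
  y3 <- 0.5 * C[, 1] + rnorm(n)
  out3 <- adjust_covariates(y3, C)
  fit1 <- lm(y3 ~ C)
  keep <- which(summary(fit1)$coefficients[-1, 4] < 0.05)
  fit2 <- lm(y3 ~ C[, keep, drop = FALSE])
  expect_equal(out3, unname(residuals(fit2)), tolerance = 1e-10)
  expect_equal(var(out3), 1, tolerance = 0.2)

  # invariants: zero mean, orthogonal to kept covariates
  expect_lt(abs(mean(out3)), 1e-10)
  for (k in keep) expect_lt(abs(sum(out3 * C[, k])), 1e-8 * n)
})

test_that("prepare_gene assembles masks, weights and counts", {
  set.seed(3)
  n <- 80
  a1 <- rpois(n, 100) + 16
  a2 <- rpois(n, 100) + 16
  cnt <- suppressWarnings(gene_counts(a1 + a2 + rpois(n, 1000), a1, a2, rep(5e7, n)))
  prep <- prepare_gene(cnt)
  expect_s3_class(prep, "prepared_gene")
  expect_equal(prep$n_trc, n)
  expect_equal(prep$n_asc, sum(prep$asc_mask))
  w <- prep$w[prep$asc_mask]
  expect_true(all(w > 0))
  expect_lte(max(w) / min(w), min(10, n / 10) + 1e-12)
  expect_lt(abs(mean(prep$y_trc[prep$trc_mask])), 1e-10)
})
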