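test_that("single_effect_regression matches the marginal-likelihood oracle", {
  set.seed(51)
  n <- 300; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- 5 * X[, 1] + rnorm(n, 0, 0.5)
  v0 <- 1
  s2 <- 0.25
  ser <- single_effect_regression(y, X, v0, sigma2 = s2)
  # independent Woodbury-form log Bayes factors
  lbf <- sapply(seq_len(p), function(j) lbf_oracle(y, X[, j], v0, s2))
  expect_equal(ser$lbf, lbf, tolerance = 1e-8)
  alpha <- exp(lbf - max(lbf)); alpha <- alpha / sum(alpha)
  expect_equal(ser$alpha, alpha, tolerance = 1e-10)
  expect_gt(ser$alpha[1], 0.95)
  expect_equal(sum(ser$alpha), 1, tolerance = 1e-12)
})

test_that("single_effect_regression degenerate cases", {
  y <- rnorm(20)
  # one variant gets all the mass
  one <- single_effect_regression(y, matrix(rnorm(20), ncol = 1), 0.2)
  expect_equal(one$alpha, 1)
  # identical columns split mass evenly
  x <- rnorm(20)
  two <- single_effect_regression(y, cbind(x, x), 0.2)
  expect_equal(two$alpha, c(0.5, 0.5), tolerance = 1e-12)
  # zero-variance column gets prior-only (uniform share of lbf = 0)
  z <- single_effect_regression(y, cbind(x, 0), 0.2)
  expect_equal(z$lbf[2], 0)
})

test_that("ibss reduces to a single effect on an orthonormal design", {
  set.seed(52)
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 8), n, 8)))
  y <- 3 * X[, 2] + rnorm(n, 0, 0.3)
  cfg <- ibss_config(L = 1, estimate_prior_variance = FALSE,
                     estimate_residual_variance = FALSE, scaled_prior = FALSE,
                     prior_variance = 1)
  fit <- ibss_fit(y, X, cfg)
  vary <- var(y) * (n - 1) / n
  ser <- single_effect_regression(y, X, 1, sigma2 = vary)
  expect_equal(fit$pip$pip, ser$alpha, tolerance = 1e-10)
})

test_that("ibss finds a strong causal variant and stays quiet on noise", {
  set.seed(53)
  n <- 400; p <- 60
  X <- matrix(rbinom(n * p, 1, 0.3) + rbinom(n * p, 1, 0.3), n, p)
  X <- scale(X, scale = FALSE)
  y <- drop(0.8 * X[, 17]) + rnorm(n)
  fit <- ibss_fit(y, X)
  expect_gt(fit$pip$pip[17], 0.9)
  expect_true(fit$converged)
  expect_equal(rowSums(fit$alpha), rep(1, nrow(fit$alpha)), tolerance = 1e-9)
  hit <- vapply(fit$credible_sets$variants, function(v) 17 %in% v, TRUE)
  expect_true(any(hit))
  expect_lte(min(fit$credible_sets$size[hit]), 5)

  # pure noise: no credible set, PIPs all small
  y0 <- rnorm(n)
  fit0 <- ibss_fit(y0, X)
  expect_equal(nrow(fit0$credible_sets), 0)
  expect_lt(max(fit0$pip$pip), 0.5)
})

test_that("duplicating a null column leaves other PIPs unchanged", {
  set.seed(54)
  n <- 200; p <- 20
  X <- matrix(rnorm(n * p), n, p)
  y <- 0.9 * X[, 3] + rnorm(n)
  f1 <- ibss_fit(y, X)
  f2 <- ibss_fit(y, cbind(X, X[, 10]))
  expect_lt(max(abs(f1$pip$pip[-10] - f2$pip$pip[seq_len(p)][-10])), 1e-6)
})

test_that("credible_set applies the cumulative and purity rules", {
  cs <- credible_set(c(0.9, 0.06, 0.04), coverage = 0.95)
  expect_equal(cs$variants, c(1, 2))
  expect_equal(cs$coverage, 0.96, tolerance = 1e-12)

  cs1 <- credible_set(c(1, 0, 0), coverage = 0.95)
  expect_equal(cs1$variants, 1)

  # a diffuse set over uncorrelated columns fails the purity filter
  set.seed(55)
  X <- matrix(rnorm(100 * 40), 100, 40)
  expect_null(credible_set(rep(1 / 40, 40), coverage = 0.95, X = X,
                           min_purity = 0.5))
})

test_that("pip_calibration bins and flags oracle PIPs correctly", {
  # perfect oracle: mass only in the extreme bins
  calib <- pip_calibration(c(rep(0, 50), rep(1, 10)),
                           c(rep(FALSE, 50), rep(TRUE, 10)))
  expect_equal(nrow(calib), 10)
  expect_equal(calib$fraction[1], 0)
  expect_equal(calib$fraction[10], 1)
  expect_true(all(is.na(calib$fraction[2:9])))
  # all-null case
  c0 <- pip_calibration(rep(0, 30), rep(FALSE, 30))
  expect_equal(c0$fraction[1], 0)
  expect_equal(sum(c0$n), 30)
})

test_that("mixfine/trcfine run on simulated genes; tidy/glance work", {
  sim <- simulate_dataset(sim_config(
    n_samples = 300, theta = 5e-5, h2 = 0.5, n_causal = 1, n_variants = 40,
    seed = 60
  ))
  prep <- prepare_gene(sim$counts, sim_filter_config())
  fit <- mixfine(prep, sim$geno)
  expect_s3_class(fit, "finemap_fit")
  expect_true(all(fit$pip$pip >= 0 & fit$pip$pip <= 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 40)
  expect_true(all(c("pip", "cs_id", "cs_size") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$p, 40)
  # the causal variant should rank near the top with h2 = 0.5
  expect_equal(which.max(fit$pip$pip), sim$truth$causal)

  # pluggable solver hook receives the stacked data
  fake <- function(y, X, cfg) list(n = length(y), p = ncol(X))
  out <- mixfine(prep, sim$geno, solver = fake)
  expect_equal(out$p, 40)
})
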