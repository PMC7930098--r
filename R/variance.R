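#' REML variance-component estimation with a genotype kernel
#'
#' Fits `y ~ N(X0 b, sigma_g^2 K + sigma_e^2 D)` with `K = X X' / p` (the
#' per-SNP random-effect kernel) and `D = diag(1/w)`, by restricted maximum
#' likelihood. Rows are pre-whitened by `sqrt(w)` so the error covariance
#' becomes the identity; the kernel spectrum is computed once and the REML
#' log-likelihood is maximized over the variance ratio
#' `delta = sigma_e^2 / sigma_g^2` on a 64-point grid over
#' `log(delta) in [-10, 10]` followed by Brent refinement in the best
#' bracket, the strategy used by eigendecomposition-based mixed-model
#' solvers. Deterministic.
#'
#' @param y Numeric response, length n (n >= 10).
#' @param X Genotype design matrix, n x p, at least one non-constant column.
#' @param w Optional positive weights (error variance `sigma_e^2 / w`);
#'   default all 1.
#' @param intercept Logical; include a fixed intercept (TRUE for the
#'   total-count block, FALSE for the imbalance block).
#' @return A list `sigma2_g`, `sigma2_e`, `delta`, `boundary` (TRUE when the
#'   optimum sits at a search boundary, reported with a warning).
#' @export
estimate_variance_components <- function(y, X, w = NULL, intercept = TRUE) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, n >= 10)
  if (is.null(w)) w <- rep(1, n)
  stopifnot(all(w > 0), length(w) == n)
  sw <- sqrt(w)
  ys <- y * sw
  Xs <- X * sw

  # fixed-effect design (whitened intercept) and its projection residual maker
  if (intercept) {
    X0 <- matrix(sw, ncol = 1)
    q <- 1L
    proj <- function(v) v - X0 %*% (crossprod(X0, v) / sum(sw^2))
  } else {
    q <- 0L
    proj <- identity
  }
  m <- n - q

  p <- ncol(X)
  if (all(apply(X, 2, var) == 0)) abort("X needs at least one non-constant column")

  # kernel K = Xs Xs' / p restricted to the fixed-effect complement; nonzero
  # spectrum obtained from the p x p cross-product for p << n
  Zs <- apply(Xs, 2, function(col) proj(col))
  Zs <- matrix(Zs, nrow = n)
  cp <- crossprod(Zs) / p
  ev <- eigen(cp, symmetric = TRUE)
  pos <- ev$values > max(ev$values, 0) * 1e-10
  r <- sum(pos)
  if (r == 0) abort("kernel is identically zero after projection")
  lambda <- ev$values[pos]
  # eigenvectors of SKS' in sample space: U = Zs V diag(1/sqrt(p*lambda))
  U <- Zs %*% ev$vectors[, pos, drop = FALSE]
  U <- sweep(U, 2, sqrt(p * lambda), "/")

  ysp <- proj(ys)
  eta2 <- drop(crossprod(U, ysp))^2
  R0 <- max(sum(ysp^2) - sum(eta2), 0)  # mass in the null-eigenvalue space

  reml_ll <- function(logd) {
    d <- exp(logd)
    ss <- sum(eta2 / (lambda + d)) + R0 / d
    logdet <- sum(log(lambda + d)) + (m - r) * logd
    0.5 * (m * log(m / (2 * pi)) - m - m * log(ss) - logdet)
  }

  grid <- seq(-10, 10, length.out = 64)
  ll <- vapply(grid, reml_ll, numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(reml_ll, interval = c(lo, hi), maximum = TRUE, tol = 1e-8)
  logd <- opt$maximum
  boundary <- i == 1 || i == length(grid)
  if (boundary) {
    # lower boundary (sigma_e -> 0) signals a degenerate fit; the upper
    # boundary just means no detectable genetic variance and is routine
    if (i == 1) warn("variance-ratio optimum at lower search boundary")
    logd <- grid[i]
  }
  d <- exp(logd)
  sigma2_g <- (sum(eta2 / (lambda + d)) + R0 / d) / m
  sigma2_e <- d * sigma2_g
  list(sigma2_g = sigma2_g, sigma2_e = sigma2_e, delta = d,
       boundary = boundary)
}

#' Estimate the two error variances of a prepared gene
#'
#' Runs [estimate_variance_components()] on the total-count block (unit
#' weights, with intercept) and on the allelic-imbalance block (capped
#' weights, no intercept) against the cis genotype designs.
#'
#' @param prep A [prepare_gene()] result.
#' @param geno Cis [phased_genotypes] over the same samples.
#' @return A list `sigma2_trc` (residual variance of the total-count
#'   equation), `sigma2_asc` (scale of the weighted imbalance error),
#'   `sigma2_g_trc`, `sigma2_g_asc`.
#' @export
estimate_gene_variances <- function(prep, geno) {
  xt <- (geno$hap1 + geno$hap2) / 2
  xa <- geno$hap1 - geno$hap2
  tm <- prep$trc_mask & rowSums(is.na(xt)) == 0
  vt <- estimate_variance_components(prep$y_trc[tm], xt[tm, , drop = FALSE],
                                     intercept = TRUE)
  am <- prep$asc_mask & rowSums(is.na(xa)) == 0
  va <- NULL
  if (sum(am) >= 10 && any(apply(xa[am, , drop = FALSE], 2, var) > 0)) {
    va <- estimate_variance_components(prep$y_asc[am], xa[am, , drop = FALSE],
                                       w = prep$w[am], intercept = FALSE)
  }
  list(
    sigma2_trc = vt$sigma2_e, sigma2_g_trc = vt$sigma2_g,
    sigma2_asc = if (is.null(va)) NA_real_ else va$sigma2_e,
    sigma2_g_asc = if (is.null(va)) NA_real_ else va$sigma2_g
  )
}

#' Stack the two equations into one homoskedastic dataset
#'
#' The total-count block is centered (response and each dosage column) and
#' divided by the estimated residual standard deviation; each
#' allelic-imbalance row is multiplied by `sqrt(w_i)/sigma_asc`. After the
#' transformation both blocks approximately satisfy `y = X beta + e` with
#' unit-variance independent errors and a shared `beta` (the trc block codes
#' dosage as `(X1+X2)/2`, the asc block as `X1-X2`), so canonical
#' fine-mapping and prediction solvers apply directly to the stacked rows.
#'
#' @param prep A [prepare_gene()] result.
#' @param geno Cis [phased_genotypes] over the same samples.
#' @param variances Optional result of [estimate_gene_variances()] (computed
#'   when missing).
#' @param include_asc Use the asc block when available (default TRUE).
#' @return A list of class `augmented_data`: `y` (stacked response), `X`
#'   (stacked design), `block` (factor `"trc"`/`"asc"` per row), `trc_center`
#'   (list with `y_mean`, `x_mean` for mapping predictions back),
#'   `variances`, `variant_id`.
#' @export
build_augmented <- function(prep, geno, variances = NULL, include_asc = TRUE) {
  if (is.null(variances)) variances <- estimate_gene_variances(prep, geno)
  if (variances$sigma2_trc <= 0) abort("non-positive total-count variance estimate")
  xt <- (geno$hap1 + geno$hap2) / 2
  tm <- prep$trc_mask & rowSums(is.na(xt)) == 0
  s0 <- sqrt(variances$sigma2_trc)
  yt <- prep$y_trc[tm]
  Xt <- xt[tm, , drop = FALSE]
  y_mean <- mean(yt)
  x_mean <- colMeans(Xt)
  y_aug <- (yt - y_mean) / s0
  X_aug <- sweep(Xt, 2, x_mean) / s0
  block <- rep("trc", length(y_aug))

  use_asc <- include_asc && is.finite(variances$sigma2_asc) &&
    variances$sigma2_asc > 0
  if (use_asc) {
    xa <- geno$hap1 - geno$hap2
    am <- prep$asc_mask & rowSums(is.na(xa)) == 0
    if (sum(am) > 0) {
      sc <- sqrt(prep$w[am]) / sqrt(variances$sigma2_asc)
      y_aug <- c(y_aug, prep$y_asc[am] * sc)
      X_aug <- rbind(X_aug, xa[am, , drop = FALSE] * sc)
      block <- c(block, rep("asc", sum(am)))
    }
  }
  structure(
    list(
      y = y_aug, X = X_aug, block = block,
      trc_center = list(y_mean = y_mean, x_mean = x_mean),
      variances = variances,
      variant_id = geno$variants$variant_id
    ),
    class = "augmented_data"
  )
}

#' @export
print.augmented_data <- function(x, ...) {
  cat(sprintf(
    "<augmented_data> %d rows (%d trc + %d asc) x %d variants\n",
    length(x$y), sum(x$block == "trc"), sum(x$block == "asc"), ncol(x$X)
  ))
  invisible(x)
}
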