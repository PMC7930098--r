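#' IBSS solver configuration
#'
#' @param L Maximum number of single effects (default 10).
#' @param prior_variance Initial effect-size prior variance, as a fraction of
#'   `var(y)` when `scaled_prior` is TRUE (default 0.2); re-estimated per
#'   effect by marginal-likelihood optimization unless
#'   `estimate_prior_variance = FALSE`.
#' @param max_iter Maximum IBSS iterations (default 100).
#' @param tol Convergence tolerance on the ELBO change (default 1e-3).
#' @param min_purity Minimum absolute within-set correlation for a credible
#'   set to be reported (default 0.5).
#' @param coverage Requested credible-set coverage (default 0.95).
#' @param estimate_prior_variance,estimate_residual_variance Logical flags.
#' @param scaled_prior Interpret `prior_variance` relative to `var(y)`.
#' @return An `ibss_config` list.
#' @export
ibss_config <- function(L = 10, prior_variance = 0.2, max_iter = 100,
                        tol = 1e-3, min_purity = 0.5, coverage = 0.95,
                        estimate_prior_variance = TRUE,
                        estimate_residual_variance = TRUE,
                        scaled_prior = TRUE) {
  stopifnot(L >= 1, tol > 0, prior_variance > 0)
  structure(
    list(
      L = L, prior_variance = prior_variance, max_iter = max_iter, tol = tol,
      min_purity = min_purity, coverage = coverage,
      estimate_prior_variance = estimate_prior_variance,
      estimate_residual_variance = estimate_residual_variance,
      scaled_prior = scaled_prior
    ),
    class = "ibss_config"
  )
}

# log Bayes factor of a single-variant effect with N(0, v0) prior, from the
# univariate summary (bhat, shat2); zero-variance columns get lbf = 0.
lbf_uni <- function(bhat, shat2, v0) {
  ok <- is.finite(shat2) & shat2 < Inf
  out <- numeric(length(bhat))
  z2 <- ifelse(ok, bhat^2 / shat2, 0)
  out[ok] <- 0.5 * log(shat2[ok] / (v0 + shat2[ok])) +
    0.5 * z2[ok] * v0 / (v0 + shat2[ok])
  out
}

#' Bayesian single-effect regression
#'
#' Exactly one of the p variants has a nonzero effect with prior
#' `N(0, prior_variance)` and uniform prior over variants. Closed form:
#' per-variant Bayes factors from the univariate regressions of `y` on each
#' column, normalized into posterior inclusion weights `alpha`.
#'
#' @param y Residualized response (length n).
#' @param X Design matrix n x p (no intercept; columns need not be scaled).
#' @param prior_variance Prior effect variance.
#' @param sigma2 Residual variance (default 1).
#' @return A list `alpha` (weights summing to 1), `mu`, `mu2` (posterior
#'   mean and second moment of the effect given inclusion), `lbf`
#'   (per-variant log Bayes factors), `lbf_model`.
#' @export
single_effect_regression <- function(y, X, prior_variance, sigma2 = 1) {
  xtx <- colSums(X^2)
  xty <- drop(crossprod(X, y))
  bhat <- ifelse(xtx > 0, xty / xtx, 0)
  shat2 <- ifelse(xtx > 0, sigma2 / xtx, Inf)
  lbf <- lbf_uni(bhat, shat2, prior_variance)
  ml <- max(lbf)
  wts <- exp(lbf - ml)
  alpha <- wts / sum(wts)
  post_var <- ifelse(xtx > 0, 1 / (1 / prior_variance + xtx / sigma2),
                     prior_variance)
  mu <- post_var * xty / sigma2
  list(
    alpha = alpha, mu = mu, mu2 = post_var + mu^2, lbf = lbf,
    lbf_model = ml + log(mean(wts))
  )
}

# optimize the single-effect prior variance by maximizing the model lbf
optimize_prior_variance <- function(bhat, shat2, v_init) {
  obj <- function(lv) {
    lbf <- lbf_uni(bhat, shat2, exp(lv))
    ml <- max(lbf)
    ml + log(mean(exp(lbf - ml)))
  }
  opt <- optimize(obj, interval = c(-30, 10), maximum = TRUE, tol = 1e-6)
  # keep the effect only if a nonzero prior beats the null (lbf 0)
  if (opt$objective <= 0) 0 else exp(opt$maximum)
}

#' Iterative Bayesian sum-of-single-effects fit
#'
#' Fits `y = X (sum_l b_l) + e`, each `b_l` having exactly one nonzero
#' coordinate, by iterative single-effect updates until the variational
#' objective (ELBO) changes by less than `tol`. Deterministic. Per-variant
#' posterior inclusion probabilities aggregate over effects as
#' `PIP_j = 1 - prod_l (1 - alpha_lj)`; effects whose optimized prior
#' variance collapses to zero, or whose inclusion weights are maximally
#' diffuse (spread over at least half the variants), are pruned from PIPs
#' and credible sets.
#'
#' @param y Response vector (an augmented-data response is already centered
#'   and scaled; no intercept is fitted).
#' @param X Design matrix.
#' @param cfg An [ibss_config].
#' @return A `finemap_fit` list: `pip` (tibble with `variant_id` if column
#'   names exist), `alpha` (L x p), `mu`, `mu2`, `prior_variance` (per
#'   effect), `sigma2`, `elbo` (trace), `converged`, `n_effects_used`,
#'   `credible_sets` (tibble), plus the inputs' dimensions.
#' @export
ibss_fit <- function(y, X, cfg = ibss_config()) {
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, n >= 2)
  L <- min(cfg$L, max(1, p))
  xtx <- colSums(X^2)
  vary <- var(y) * (n - 1) / n
  v0 <- if (cfg$scaled_prior) cfg$prior_variance * vary else cfg$prior_variance
  v0 <- max(v0, .Machine$double.eps)

  alpha <- matrix(1 / p, L, p)
  mu <- matrix(0, L, p)
  mu2 <- matrix(0, L, p)
  V <- rep(v0, L)
  lbf_model <- rep(0, L)
  sigma2 <- max(vary, .Machine$double.eps)
  Xb_l <- matrix(0, n, L)      # per-effect fitted values X (alpha*mu)
  elbo <- numeric(0)
  converged <- FALSE

  for (it in seq_len(cfg$max_iter)) {
    for (l in seq_len(L)) {
      r_l <- y - rowSums(Xb_l[, -l, drop = FALSE])
      xty <- drop(crossprod(X, r_l))
      bhat <- ifelse(xtx > 0, xty / xtx, 0)
      shat2 <- ifelse(xtx > 0, sigma2 / xtx, Inf)
      if (cfg$estimate_prior_variance) {
        V[l] <- optimize_prior_variance(bhat, shat2, V[l])
      }
      if (V[l] <= 0) {
        alpha[l, ] <- 1 / p
        mu[l, ] <- 0
        mu2[l, ] <- 0
        lbf_model[l] <- 0
        Xb_l[, l] <- 0
        next
      }
      ser <- single_effect_regression(r_l, X, V[l], sigma2)
      alpha[l, ] <- ser$alpha
      mu[l, ] <- ser$mu
      mu2[l, ] <- ser$mu2
      lbf_model[l] <- ser$lbf_model
      Xb_l[, l] <- drop(X %*% (ser$alpha * ser$mu))
    }
    # ELBO and residual-variance update
    r <- y - rowSums(Xb_l)
    erss <- sum(r^2) +
      sum(vapply(seq_len(L), function(l) {
        sum(xtx * alpha[l, ] * mu2[l, ]) - sum(Xb_l[, l]^2)
      }, numeric(1)))
    kl <- vapply(seq_len(L), function(l) {
      r_l <- y - rowSums(Xb_l[, -l, drop = FALSE])
      loglik_ser <- lbf_model[l] - 0.5 * n * log(2 * pi * sigma2) -
        0.5 * sum(r_l^2) / sigma2
      eb <- alpha[l, ] * mu[l, ]
      eb2 <- alpha[l, ] * mu2[l, ]
      e_loglik <- -0.5 * n * log(2 * pi * sigma2) -
        0.5 / sigma2 * (sum(r_l^2) - 2 * sum(r_l * (X %*% eb)) + sum(xtx * eb2))
      e_loglik - loglik_ser
    }, numeric(1))
    obj <- -0.5 * n * log(2 * pi * sigma2) - 0.5 * erss / sigma2 - sum(kl)
    elbo <- c(elbo, obj)
    if (it > 1 && abs(elbo[it] - elbo[it - 1]) < cfg$tol) {
      converged <- TRUE
      break
    }
    if (cfg$estimate_residual_variance) {
      sigma2 <- max(erss / n, .Machine$double.eps)
    }
  }

  # prune effects that are null (prior variance collapsed) or maximally
  # diffuse (inclusion mass spread over at least half the variants, measured
  # by the participation ratio 1/sum(alpha^2))
  pr <- 1 / rowSums(alpha^2)
  active <- V > 1e-9 & pr <= pmax(2, p / 2)
  pip <- if (any(active)) {
    1 - apply(1 - alpha[active, , drop = FALSE], 2, prod)
  } else {
    rep(0, p)
  }
  ids <- colnames(X) %||% paste0("v", seq_len(p))
  cs <- credible_sets_from_alpha(alpha, active, X, cfg)
  structure(
    list(
      pip = tibble::tibble(variant_id = ids, pip = pip),
      alpha = alpha, mu = mu, mu2 = mu2, prior_variance = V,
      sigma2 = sigma2, elbo = elbo, converged = converged,
      n_effects_used = sum(active), credible_sets = cs,
      n = n, p = p
    ),
    class = "finemap_fit"
  )
}

#' Credible set of one single-effect component
#'
#' Sorts variants by inclusion weight (ties broken by index), takes the
#' minimal prefix with cumulative weight at or above `coverage`, and
#' discards the set when the minimum pairwise absolute correlation between
#' member columns of `X` falls below `min_purity`.
#'
#' @param alpha_l Inclusion-weight vector of one effect (sums to 1).
#' @param coverage Requested coverage (default 0.95).
#' @param X Design matrix used for the purity computation.
#' @param min_purity Purity threshold (default 0.5).
#' @return A list `variants` (indices), `coverage` (attained), `purity`, or
#'   NULL when discarded.
#' @export
credible_set <- function(alpha_l, coverage = 0.95, X = NULL, min_purity = 0.5) {
  ord <- order(-alpha_l, seq_along(alpha_l))
  cum <- cumsum(alpha_l[ord])
  k <- which(cum >= coverage)[1]
  if (is.na(k)) k <- length(ord)
  idx <- sort(ord[seq_len(k)])
  purity <- 1
  if (!is.null(X) && length(idx) > 1) {
    cc <- suppressWarnings(cor(X[, idx, drop = FALSE]))
    cc[!is.finite(cc)] <- 0
    purity <- min(abs(cc[upper.tri(cc)]))
  }
  if (purity < min_purity) return(NULL)
  list(variants = idx, coverage = cum[k], purity = purity)
}

credible_sets_from_alpha <- function(alpha, active, X, cfg) {
  rows <- list()
  seen <- character(0)
  for (l in which(active)) {
    cs <- credible_set(alpha[l, ], cfg$coverage, X, cfg$min_purity)
    if (is.null(cs)) next
    key <- paste(cs$variants, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(rows) + 1]] <- tibble::tibble(
      cs_id = length(rows) + 1L,
      effect = l,
      variants = list(cs$variants),
      size = length(cs$variants),
      requested_coverage = cfg$coverage,
      coverage = cs$coverage,
      purity = cs$purity
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      cs_id = integer(), effect = integer(), variants = list(),
      size = integer(), requested_coverage = numeric(),
      coverage = numeric(), purity = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Fine-map a gene on the augmented data
#'
#' Estimates the two error variances, stacks the variance-standardized
#' total-count and allelic-imbalance blocks and runs the sum-of-single-
#' effects solver (`trcfine()` uses the total-count block only). A different
#' solver with the same signature `function(y, X, cfg)` can be plugged in
#' via `solver`.
#'
#' @param prep A [prepare_gene()] result.
#' @param geno Cis [phased_genotypes].
#' @param cfg An [ibss_config].
#' @param solver Solver function (default [ibss_fit]).
#' @return A `finemap_fit` (see [ibss_fit()]).
#' @export
mixfine <- function(prep, geno, cfg = ibss_config(), solver = ibss_fit) {
  aug <- build_augmented(prep, geno, include_asc = TRUE)
  solver(aug$y, aug$X, cfg)
}

#' @rdname mixfine
#' @export
trcfine <- function(prep, geno, cfg = ibss_config(), solver = ibss_fit) {
  aug <- build_augmented(prep, geno, include_asc = FALSE)
  solver(aug$y, aug$X, cfg)
}

#' @export
print.finemap_fit <- function(x, ...) {
  cat(sprintf(
    "<finemap_fit> %d variants, %d effect(s) used, %d credible set(s), converged=%s\n",
    x$p, x$n_effects_used, nrow(x$credible_sets), x$converged
  ))
  invisible(x)
}

#' PIP calibration table
#'
#' Bins variants by posterior inclusion probability (10 equal bins) and
#' tabulates the observed fraction of truly causal variants per bin with a
#' Wilson binomial confidence interval.
#'
#' @param pips Numeric vector of PIPs pooled over simulations.
#' @param causal Logical vector, TRUE for truly causal variants.
#' @param bins Number of bins (default 10).
#' @return A tibble with `bin`, `bin_lo`, `bin_hi`, `bin_mid`, `n`,
#'   `n_causal`, `fraction`, `ci_lo`, `ci_hi`.
#' @export
pip_calibration <- function(pips, causal, bins = 10) {
  stopifnot(length(pips) == length(causal))
  br <- seq(0, 1, length.out = bins + 1)
  idx <- pmin(findInterval(pips, br, rightmost.closed = TRUE), bins)
  purrr::map_dfr(seq_len(bins), function(b) {
    sel <- idx == b
    n <- sum(sel)
    k <- sum(causal[sel])
    ci <- wilson_ci(k, n)
    tibble::tibble(
      bin = b, bin_lo = br[b], bin_hi = br[b + 1],
      bin_mid = (br[b] + br[b + 1]) / 2,
      n = n, n_causal = k,
      fraction = if (n > 0) k / n else NA_real_,
      ci_lo = ci[1], ci_hi = ci[2]
    )
  })
}
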