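#' Train a penalized prediction model on the augmented data
#'
#' Elastic-net path (via glmnet, no internal intercept or standardization:
#' the augmented rows are already centered/scaled and the two blocks share
#' one coefficient vector) over the stacked total-count and
#' allelic-imbalance rows. The penalty is selected by internal k-fold
#' cross-validation minimizing mean squared error on total-count rows only,
#' since the deployable prediction target lives on the total-count scale;
#' allelic-imbalance rows of held-in samples still inform each fold's fit.
#' Folds are formed over samples so a held-out sample contributes no row of
#' either block.
#'
#' @param aug An [build_augmented()] result (or any list with `y`, `X`,
#'   `block`, `trc_center`, `variant_id`).
#' @param alpha_mix Elastic-net mixing parameter in `[0, 1]` (default 0.5).
#' @param n_lambda Path length (default 100).
#' @param lambda Optional user-supplied penalty sequence overriding the
#'   automatic path (a single value skips the internal CV).
#' @param n_folds Internal CV folds (default 5).
#' @param sample_id Optional integer vector mapping augmented rows to sample
#'   indices; defaults to row order within block (valid for
#'   [build_augmented()] output when masks are taken from one gene).
#' @param seed Seed for the fold assignment (default 1).
#' @return A `mixpred_model`: `weights` (tibble variant_id, weight on the
#'   per-allele log scale), `intercept`, `alpha_mix`, `lambda`, `cv_mse`
#'   (tibble lambda x mse).
#' @export
fit_mixpred <- function(aug, alpha_mix = 0.5, n_lambda = 100, lambda = NULL,
                        n_folds = 5, sample_id = NULL, seed = 1) {
  y <- aug$y
  X <- aug$X
  n <- length(y)
  stopifnot(n >= 20)
  trc_rows <- which(aug$block == "trc")
  if (sd(y[trc_rows]) == 0) {
    return(new_mixpred_model(
      weights = rep(0, ncol(X)), aug = aug, alpha_mix = alpha_mix,
      lambda = Inf, cv_mse = tibble::tibble(lambda = numeric(), mse = numeric())
    ))
  }

  fit_all <- if (is.null(lambda)) {
    glmnet::glmnet(X, y, family = "gaussian", alpha = alpha_mix,
                   nlambda = n_lambda, intercept = FALSE, standardize = FALSE)
  } else {
    glmnet::glmnet(X, y, family = "gaussian", alpha = alpha_mix,
                   lambda = sort(lambda, decreasing = TRUE),
                   intercept = FALSE, standardize = FALSE)
  }
  lambdas <- fit_all$lambda
  if (length(lambdas) == 1) {
    wts <- as.numeric(coef(fit_all, s = lambdas))[-1]
    return(new_mixpred_model(
      weights = wts, aug = aug, alpha_mix = alpha_mix, lambda = lambdas,
      cv_mse = tibble::tibble(lambda = numeric(), mse = numeric())
    ))
  }

  if (is.null(sample_id)) {
    sample_id <- integer(n)
    sample_id[trc_rows] <- seq_along(trc_rows)
    # asc rows correspond to a subset of the trc samples only when masks
    # align; fall back to independent ids so folds never split a row pair
    sample_id[aug$block == "asc"] <- seq_len(sum(aug$block == "asc")) +
      max(sample_id)
  }
  usamp <- unique(sample_id[trc_rows])
  old <- local_seed(seed)
  fold_of <- sample(rep_len(seq_len(n_folds), length(usamp)))
  restore_seed(old)
  names(fold_of) <- as.character(usamp)

  mse <- matrix(NA_real_, n_folds, length(lambdas))
  for (k in seq_len(n_folds)) {
    held_samples <- usamp[fold_of[as.character(usamp)] == k]
    test_rows <- intersect(which(sample_id %in% held_samples), trc_rows)
    train_rows <- which(!sample_id %in% held_samples)
    if (length(test_rows) == 0 || length(train_rows) < 2) next
    fit_k <- glmnet::glmnet(
      X[train_rows, , drop = FALSE], y[train_rows], family = "gaussian",
      alpha = alpha_mix, lambda = lambdas, intercept = FALSE,
      standardize = FALSE
    )
    pred <- predict(fit_k, X[test_rows, , drop = FALSE])
    err <- (pred - y[test_rows])^2
    mse[k, seq_len(ncol(pred))] <- colMeans(err)
  }
  mmse <- colMeans(mse, na.rm = TRUE)
  best <- which.min(mmse)
  lambda <- lambdas[best]
  wts <- as.numeric(coef(fit_all, s = lambda))[-1]  # drop (zero) intercept
  new_mixpred_model(
    weights = wts, aug = aug, alpha_mix = alpha_mix, lambda = lambda,
    cv_mse = tibble::tibble(lambda = lambdas, mse = mmse)
  )
}

new_mixpred_model <- function(weights, aug, alpha_mix, lambda, cv_mse) {
  # augmented scaling leaves beta on the per-allele log scale; the intercept
  # restores the centering of the trc block on the observable scale
  intercept <- aug$trc_center$y_mean - sum(aug$trc_center$x_mean * weights)
  structure(
    list(
      weights = tibble::tibble(variant_id = aug$variant_id, weight = weights),
      intercept = intercept, alpha_mix = alpha_mix, lambda = lambda,
      cv_mse = cv_mse
    ),
    class = "mixpred_model"
  )
}

#' @export
print.mixpred_model <- function(x, ...) {
  cat(sprintf(
    "<mixpred_model> %d variants (%d nonzero), lambda=%.4g\n",
    nrow(x$weights), sum(x$weights$weight != 0), x$lambda
  ))
  invisible(x)
}

#' Predict log total-count abundance from genotypes
#'
#' `yhat_i = intercept + sum_j ((X1_ij + X2_ij)/2) * weight_j`. Model
#' variants missing from `geno` are dropped with a warning.
#'
#' @param object A `mixpred_model`.
#' @param geno A [phased_genotypes] object.
#' @param ... Unused.
#' @return Numeric predictions, one per sample.
#' @export
predict.mixpred_model <- function(object, geno, ...) {
  w <- object$weights
  hit <- w$variant_id %in% geno$variants$variant_id
  if (!all(hit)) {
    warn(sprintf("%d model variant(s) missing from genotypes; weights dropped",
                 sum(!hit)))
    w <- w[hit, ]
  }
  if (nrow(w) == 0) {
    return(rep(object$intercept, n_samples(geno)))
  }
  j <- match(w$variant_id, geno$variants$variant_id)
  xbar <- (geno$hap1[, j, drop = FALSE] + geno$hap2[, j, drop = FALSE]) / 2
  drop(object$intercept + xbar %*% w$weight)
}

#' Cross-validated prediction evaluation
#'
#' Splits the samples into `k` folds; at each fold the model is trained on
#' that single fold and evaluated (Pearson correlation between predicted
#' and observed covariate-adjusted `log(total/(2*libsize))`) on the
#' remaining k-1 folds, so a larger `k` means a smaller training set.
#' Both the combined (augmented) model and the total-count-only model are
#' evaluated on identical splits.
#'
#' @param counts A [gene_counts] object.
#' @param geno Cis [phased_genotypes].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed controlling the fold assignment.
#' @param cfg A [filter_config].
#' @param covariates Optional covariates for the response adjustment.
#' @param alpha_mix Elastic-net mixing parameter.
#' @return A tibble with one row per fold and method: `fold`, `method`
#'   (`"mixpred"`/`"trcpred"`), `n_train`, `n_test`, `r`.
#' @export
crossval_evaluate <- function(counts, geno, k = 5, seed = 1,
                              cfg = filter_config(), covariates = NULL,
                              alpha_mix = 0.5) {
  stopifnot(k >= 2)
  n <- length(counts$total)
  old <- local_seed(seed)
  fold_of <- sample(rep_len(seq_len(k), n))
  restore_seed(old)
  purrr::map_dfr(seq_len(k), function(f) {
    train <- which(fold_of == f)
    test <- which(fold_of != f)
    evaluate_split(counts, geno, train, test, cfg, covariates, alpha_mix,
                   fold = f)
  })
}

# train on `train` indices, report held-out Pearson r for both methods
evaluate_split <- function(counts, geno, train, test, cfg, covariates,
                           alpha_mix, fold = 1L, seed = 1) {
  sub <- function(idx) {
    gene_counts(counts$total[idx], counts$asc1[idx], counts$asc2[idx],
                counts$libsize[idx])
  }
  prep_tr <- prepare_gene(sub(train), cfg,
                          if (is.null(covariates)) NULL else
                            as.matrix(covariates)[train, , drop = FALSE])
  geno_tr <- subset_samples(geno, train)
  geno_te <- subset_samples(geno, test)
  y_te <- log(pmax(counts$total[test], cfg$trc_zero_impute) /
                (2 * counts$libsize[test]))
  y_te <- adjust_covariates(
    y_te,
    if (is.null(covariates)) NULL else as.matrix(covariates)[test, , drop = FALSE]
  )
  one <- function(include_asc, method) {
    r <- NA_real_
    fit_ok <- tryCatch({
      aug <- build_augmented(prep_tr, geno_tr, include_asc = include_asc)
      m <- fit_mixpred(aug, alpha_mix = alpha_mix, seed = seed)
      pred <- predict(m, geno_te)
      if (sd(y_te, na.rm = TRUE) > 0 && sd(pred) > 0) {
        r <- cor(pred, y_te, use = "complete.obs")
      }
      TRUE
    }, error = function(e) FALSE)
    tibble::tibble(
      fold = fold, method = method, n_train = length(train),
      n_test = length(test), r = r
    )
  }
  dplyr::bind_rows(
    one(TRUE, "mixpred"),
    one(FALSE, "trcpred")
  )
}
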