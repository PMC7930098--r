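#' Filtering and weighting configuration
#'
#' Defaults follow the GTEx-style run of the method: per-sample
#' allele-specific counts must exceed `asc_sample_min_reads` on both
#' haplotypes and stay at or below `asc_outlier_max` (larger counts are
#' treated as likely alignment artifacts); zero total counts are imputed to
#' `trc_zero_impute` before taking logs; the optional gene-level filter asks
#' for at least `gene_min_asc_samples` samples with at least
#' `gene_asc_reads_per_hap` allele-specific reads per haplotype and at least
#' `gene_min_trc_samples` samples with total count at least
#' `gene_trc_min_reads`. The allelic-imbalance component enters the
#' meta-analysis only when at least `min_asc_samples_for_meta` samples
#' qualify.
#'
#' @param asc_sample_min_reads Per-sample strict lower bound on both
#'   haplotype asc counts (default 15; inclusion requires `> 15`).
#' @param asc_outlier_max Per-sample upper bound on either haplotype asc
#'   count (default 1000).
#' @param trc_zero_impute Value substituted for zero total counts (default 1).
#' @param gene_min_asc_samples,gene_asc_reads_per_hap Gene-level asc
#'   inclusion criteria (defaults 15 samples at >= 50 reads per haplotype).
#' @param gene_min_trc_samples,gene_trc_min_reads Gene-level total-count
#'   criteria (defaults 500 samples at total >= 100).
#' @param min_asc_samples_for_meta Minimum qualifying samples for the asc
#'   regression to be fitted (default 15).
#'
#' @return A `filter_config` list.
#' @export
filter_config <- function(asc_sample_min_reads = 15,
                          asc_outlier_max = 1000,
                          trc_zero_impute = 1,
                          gene_min_asc_samples = 15,
                          gene_asc_reads_per_hap = 50,
                          gene_min_trc_samples = 500,
                          gene_trc_min_reads = 100,
                          min_asc_samples_for_meta = 15) {
  cfg <- list(
    asc_sample_min_reads = asc_sample_min_reads,
    asc_outlier_max = asc_outlier_max,
    trc_zero_impute = trc_zero_impute,
    gene_min_asc_samples = gene_min_asc_samples,
    gene_asc_reads_per_hap = gene_asc_reads_per_hap,
    gene_min_trc_samples = gene_min_trc_samples,
    gene_trc_min_reads = gene_trc_min_reads,
    min_asc_samples_for_meta = min_asc_samples_for_meta
  )
  if (any(unlist(cfg) < 0)) abort("filter thresholds must be >= 0")
  structure(cfg, class = "filter_config")
}

#' Log total-count abundance
#'
#' Computes `y_trc = log(max(total, impute) / (2 * libsize))`, the log of
#' per-haplotype-scaled relative abundance used as the total-read-count
#' regression response.
#'
#' @param counts A [gene_counts] object.
#' @param cfg A [filter_config].
#' @return A list with `y_trc` (numeric) and `trc_mask` (logical; TRUE
#'   wherever the library size is defined and positive).
#' @export
compute_trc <- function(counts, cfg = filter_config()) {
  mask <- is.finite(counts$libsize) & counts$libsize > 0
  y <- rep(NA_real_, length(counts$total))
  y[mask] <- log(pmax(counts$total[mask], cfg$trc_zero_impute) /
                   (2 * counts$libsize[mask]))
  list(y_trc = y, trc_mask = mask)
}

#' Allelic imbalance and raw precision weights
#'
#' `y_asc = log(asc1/asc2)` with raw weight `(1/asc1 + 1/asc2)^(-1)`
#' (the inverse of the count-scaled error variance). A sample qualifies when
#' both haplotype counts strictly exceed `asc_sample_min_reads` and neither
#' exceeds `asc_outlier_max`.
#'
#' @inheritParams compute_trc
#' @return A list with `y_asc`, `raw_w` (NA outside the mask) and `asc_mask`.
#' @export
compute_asc <- function(counts, cfg = filter_config()) {
  a1 <- counts$asc1
  a2 <- counts$asc2
  mask <- a1 > cfg$asc_sample_min_reads & a2 > cfg$asc_sample_min_reads &
    pmax(a1, a2) <= cfg$asc_outlier_max
  mask[is.na(mask)] <- FALSE
  y <- w <- rep(NA_real_, length(a1))
  y[mask] <- log(a1[mask] / a2[mask])
  w[mask] <- 1 / (1 / a1[mask] + 1 / a2[mask])
  list(y_asc = y, raw_w = w, asc_mask = mask)
}

#' Cap precision weights
#'
#' Limits every weight to at most `K = min(10, n/10)` times the smallest
#' weight, damping the influence of samples with very large allele-specific
#' counts on the imbalance fit. `K` is floored at 1 (degenerate tiny-n guard:
#' all weights equalized).
#'
#' @param raw_w Positive raw weights (only the qualifying samples).
#' @param n Sample size used to set the cap (the number of samples in the
#'   study, not the number of qualifying samples).
#' @return Capped weights, same length as `raw_w`.
#' @export
cap_weights <- function(raw_w, n) {
  if (length(raw_w) == 0) return(raw_w)
  stopifnot(all(raw_w > 0))
  K <- max(1, min(10, n / 10))
  pmin(raw_w, K * min(raw_w))
}

#' Gene-level allele-specific coverage filter
#'
#' @inheritParams compute_trc
#' @return TRUE iff at least `gene_min_asc_samples` samples have both
#'   haplotype asc counts `>= gene_asc_reads_per_hap` and at least
#'   `gene_min_trc_samples` samples have total count
#'   `>= gene_trc_min_reads`.
#' @export
gene_passes_asc_filters <- function(counts, cfg = filter_config()) {
  n_asc <- sum(counts$asc1 >= cfg$gene_asc_reads_per_hap &
                 counts$asc2 >= cfg$gene_asc_reads_per_hap)
  n_trc <- sum(counts$total >= cfg$gene_trc_min_reads)
  n_asc >= cfg$gene_min_asc_samples && n_trc >= cfg$gene_min_trc_samples
}

#' Two-stage covariate adjustment of the total-count response
#'
#' Stage 1 regresses `y_trc` on all covariates jointly (with intercept) and
#' keeps those with two-sided coefficient p < `p_keep`; stage 2 regresses on
#' the kept covariates and returns the residuals. With no covariate kept the
#' centered response is returned. Allelic-imbalance values are never
#' covariate-adjusted: individual-level effects cancel in the haplotype
#' ratio.
#'
#' @param y_trc Numeric response (NAs allowed; they propagate).
#' @param covariates A data frame or matrix of sample-by-covariate values,
#'   or NULL.
#' @param p_keep Selection threshold (default 0.05).
#' @return Residual vector, same length as `y_trc`, with zero mean over the
#'   non-missing entries.
#' @export
adjust_covariates <- function(y_trc, covariates, p_keep = 0.05) {
  obs <- is.finite(y_trc)
  out <- rep(NA_real_, length(y_trc))
  if (is.null(covariates) || ncol(as.matrix(covariates)) == 0) {
    out[obs] <- y_trc[obs] - mean(y_trc[obs])
    return(out)
  }
  C <- as.matrix(covariates)
  if (is.null(colnames(C))) colnames(C) <- paste0("c", seq_len(ncol(C)))
  # drop constant columns up front
  keep_col <- apply(C[obs, , drop = FALSE], 2, function(v) sd(v) > 0)
  if (!all(keep_col)) {
    warn(sprintf("dropping %d constant covariate(s)", sum(!keep_col)))
    C <- C[, keep_col, drop = FALSE]
  }
  if (ncol(C) == 0) {
    out[obs] <- y_trc[obs] - mean(y_trc[obs])
    return(out)
  }
  if (sum(obs) <= ncol(C) + 1) abort("need n > K + 1 samples for covariate adjustment")

  df1 <- data.frame(y = y_trc[obs], C[obs, , drop = FALSE])
  fit1 <- lm(y ~ ., data = df1)
  ct <- summary(fit1)$coefficients
  pvals <- ct[rownames(ct) != "(Intercept)", 4]
  kept <- names(pvals)[pvals < p_keep & !is.na(pvals)]
  if (length(kept) == 0) {
    out[obs] <- y_trc[obs] - mean(y_trc[obs])
    return(out)
  }
  df2 <- df1[, c("y", kept), drop = FALSE]
  fit2 <- lm(y ~ ., data = df2)
  if (any(is.na(coef(fit2)))) {
    warn("rank-deficient stage-2 design; collinear covariates dropped")
  }
  out[obs] <- residuals(fit2)
  out
}

#' Prepare a gene's regression quantities
#'
#' Runs [compute_trc()], [compute_asc()], [cap_weights()] and (optionally)
#' [adjust_covariates()] for one gene.
#'
#' @inheritParams compute_trc
#' @param covariates Optional sample-by-covariate matrix/data frame.
#' @return A `prepared_gene` list: `y_trc`, `trc_mask`, `y_asc`, `w` (capped,
#'   NA outside mask), `asc_mask`, `n_trc`, `n_asc`, `n` (study sample size).
#' @export
prepare_gene <- function(counts, cfg = filter_config(), covariates = NULL) {
  n <- length(counts$total)
  trc <- compute_trc(counts, cfg)
  asc <- compute_asc(counts, cfg)
  y_trc <- adjust_covariates(trc$y_trc, covariates)
  w <- asc$raw_w
  w[asc$asc_mask] <- cap_weights(asc$raw_w[asc$asc_mask], n)
  structure(
    list(
      y_trc = y_trc, trc_mask = trc$trc_mask & is.finite(y_trc),
      y_asc = asc$y_asc, w = w, asc_mask = asc$asc_mask,
      n_trc = sum(trc$trc_mask & is.finite(y_trc)),
      n_asc = sum(asc$asc_mask), n = n
    ),
    class = "prepared_gene"
  )
}

#' @export
print.prepared_gene <- function(x, ...) {
  cat(sprintf(
    "<prepared_gene> n=%d, n_trc=%d, n_asc=%d\n", x$n, x$n_trc, x$n_asc
  ))
  invisible(x)
}
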