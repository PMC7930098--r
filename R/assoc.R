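#' Total-read-count regression for one variant
#'
#' Ordinary least squares of the (covariate-adjusted) log total-count
#' abundance on the average haplotype dosage `x_trc = (X1 + X2)/2`, with
#' intercept. The error term absorbs both baseline-abundance variation and
#' count noise and is treated as homoskedastic.
#'
#' @param y Numeric response.
#' @param x Average allele dosage per sample (0, 0.5 or 1).
#' @return A list `beta`, `se`, `p` (two-sided, t with n-2 df), `n`. All NA
#'   when fewer than 3 complete samples or the variant is monomorphic.
#' @export
fit_trc <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  n <- length(y)
  if (n < 3 || var(x) == 0) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n))
  }
  xc <- x - mean(x)
  yc <- y - mean(y)
  sxx <- sum(xc^2)
  beta <- sum(xc * yc) / sxx
  res <- yc - beta * xc
  s2 <- sum(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tval <- beta / se
  list(beta = beta, se = se, p = 2 * pt(-abs(tval), df = n - 2), n = n)
}

#' Weighted allelic-imbalance regression for one variant
#'
#' Weighted least squares of the log haplotype-count ratio on the haplotype
#' dosage difference `x_asc = X1 - X2`, through the origin (the individual
#' baseline cancels in the ratio, so no intercept). Weights are the capped
#' inverse count variances.
#'
#' @param y Log allelic-imbalance values (qualifying samples).
#' @param x Haplotype dosage differences in \{-1, 0, 1\}.
#' @param w Positive weights.
#' @return A list `beta`, `se`, `p` (two-sided, t with n-1 df), `n`. All NA
#'   when fewer than 2 complete samples carry a heterozygous dosage
#'   difference.
#' @export
fit_asc <- function(y, x, w) {
  ok <- is.finite(y) & is.finite(x) & is.finite(w)
  y <- y[ok]; x <- x[ok]; w <- w[ok]
  n <- length(y)
  if (n < 2 || sum(x != 0) < 2) {
    return(list(beta = NA_real_, se = NA_real_, p = NA_real_, n = n))
  }
  swx2 <- sum(w * x^2)
  beta <- sum(w * x * y) / swx2
  s2 <- sum(w * (y - x * beta)^2) / (n - 1)
  se <- sqrt(s2 / swx2)
  tval <- beta / se
  list(beta = beta, se = se, p = 2 * pt(-abs(tval), df = n - 1), n = n)
}

#' Inverse-variance meta-analysis of the two component estimates
#'
#' Standard fixed-effect combination of the total-count and
#' allelic-imbalance estimates, treated as independent studies. The p-value
#' is normal-based.
#'
#' @param beta1,se1 First component estimate and standard error.
#' @param beta2,se2 Second component estimate and standard error.
#' @return A list `beta`, `se`, `p`. If one component is NA the other is
#'   returned unchanged (with its normal-based p); if both are NA, all NA.
#' @export
meta_combine <- function(beta1, se1, beta2, se2) {
  ok1 <- is.finite(beta1) && is.finite(se1) && se1 > 0
  ok2 <- is.finite(beta2) && is.finite(se2) && se2 > 0
  if (!ok1 && !ok2) return(list(beta = NA_real_, se = NA_real_, p = NA_real_))
  if (ok1 && !ok2) {
    return(list(beta = beta1, se = se1, p = 2 * pnorm(-abs(beta1 / se1))))
  }
  if (!ok1 && ok2) {
    return(list(beta = beta2, se = se2, p = 2 * pnorm(-abs(beta2 / se2))))
  }
  v1 <- 1 / se1^2
  v2 <- 1 / se2^2
  beta <- (v1 * beta1 + v2 * beta2) / (v1 + v2)
  se <- 1 / sqrt(v1 + v2)
  list(beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)))
}

#' Single-variant cis scan for one gene
#'
#' For every variant: the total-count regression is always attempted; the
#' allelic-imbalance regression is fitted only when at least
#' `min_asc_samples_for_meta` samples qualify and at least one carries a
#' nonzero dosage difference; the two are combined by inverse-variance
#' meta-analysis when both are defined, otherwise the defined component is
#' reported (`method` records which). Samples with a missing genotype are
#' dropped for that variant only.
#'
#' @param prep A [prepare_gene()] result.
#' @param geno A [phased_genotypes] object over the same samples (cis-window
#'   subset).
#' @param cfg A [filter_config].
#' @return A tibble, one row per variant, with columns `variant_id`,
#'   `n_trc`, `n_asc`, `beta_trc`, `se_trc`, `p_trc`, `beta_asc`, `se_asc`,
#'   `p_asc`, `beta_meta`, `se_meta`, `p_meta`, `method`.
#' @export
run_cis_scan <- function(prep, geno, cfg = filter_config()) {
  stopifnot(inherits(prep, "prepared_gene"), inherits(geno, "phased_genotypes"))
  if (n_samples(geno) != prep$n) {
    abort("genotype and count sample dimensions differ")
  }
  p <- n_variants(geno)
  res <- purrr::map(seq_len(p), function(j) {
    h1 <- geno$hap1[, j]
    h2 <- geno$hap2[, j]
    x_trc <- (h1 + h2) / 2
    x_asc <- h1 - h2
    trc <- fit_trc(prep$y_trc[prep$trc_mask], x_trc[prep$trc_mask])
    am <- prep$asc_mask
    asc <- list(beta = NA_real_, se = NA_real_, p = NA_real_,
                n = sum(am & is.finite(x_asc)))
    if (prep$n_asc >= cfg$min_asc_samples_for_meta &&
        sum(am & is.finite(x_asc) & x_asc != 0) >= 2) {
      asc <- fit_asc(prep$y_asc[am], x_asc[am], prep$w[am])
    }
    meta <- meta_combine(trc$beta, trc$se, asc$beta, asc$se)
    method <- if (is.finite(trc$beta) && is.finite(asc$beta)) {
      "meta"
    } else if (is.finite(trc$beta)) {
      "trc"
    } else if (is.finite(asc$beta)) {
      "asc"
    } else {
      NA_character_
    }
    tibble::tibble(
      variant_id = geno$variants$variant_id[j],
      n_trc = trc$n, n_asc = asc$n,
      beta_trc = trc$beta, se_trc = trc$se, p_trc = trc$p,
      beta_asc = asc$beta, se_asc = asc$se, p_asc = asc$p,
      beta_meta = meta$beta, se_meta = meta$se, p_meta = meta$p,
      method = method
    )
  })
  dplyr::bind_rows(res)
}

#' Multi-gene cis scan
#'
#' Convenience wrapper: for each annotated gene, extracts the cis-window,
#' prepares the counts and runs the single-gene scan.
#'
#' @param geno A [phased_genotypes] object (all variants).
#' @param counts A named list of [gene_counts] (as from
#'   [read_count_tables()]).
#' @param annotation A tibble with `gene_id`, `chrom`, `tss`.
#' @param covariates Optional covariate matrix/data frame.
#' @param cfg A [filter_config].
#' @param window Cis-window half-width in bp.
#' @return A tibble of per-variant results with a leading `gene_id` column.
#' @export
mixqtl_scan <- function(geno, counts, annotation, covariates = NULL,
                        cfg = filter_config(), window = 1e6) {
  annotation <- tibble::as_tibble(annotation)
  res <- purrr::map(seq_len(nrow(annotation)), function(i) {
    g <- annotation$gene_id[i]
    if (!g %in% names(counts)) return(NULL)
    win <- cis_window(annotation[i, ], geno, window)
    if (n_variants(win) == 0) return(NULL)
    prep <- prepare_gene(counts[[g]], cfg, covariates)
    dplyr::mutate(run_cis_scan(prep, win, cfg), gene_id = g, .before = 1)
  })
  dplyr::bind_rows(res)
}

#' Permute a prepared gene
#'
#' Applies one shared random permutation of sample indices to the
#' total-count quantities and an independent one to the allelic-imbalance
#' quantities, breaking the genotype-phenotype linkage while preserving the
#' marginal distributions. Deterministic given `seed`.
#'
#' @param prep A [prepare_gene()] result.
#' @param seed Integer seed.
#' @return A permuted `prepared_gene`.
#' @export
permute_gene <- function(prep, seed) {
  n <- prep$n
  perm <- function(v, idx) v[idx]
  out <- prep
  old <- local_seed(seed)
  idx_trc <- sample.int(n)
  idx_asc <- sample.int(n)
  restore_seed(old)
  out$y_trc <- perm(prep$y_trc, idx_trc)
  out$trc_mask <- perm(prep$trc_mask, idx_trc)
  out$y_asc <- perm(prep$y_asc, idx_asc)
  out$w <- perm(prep$w, idx_asc)
  out$asc_mask <- perm(prep$asc_mask, idx_asc)
  out
}

# Set the RNG state from a seed, returning the previous state so callers do
# not disturb the global stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
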