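#' Wilson score interval
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return `c(lo, hi)`; `c(NA, NA)` when `n = 0`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  lo <- if (k == 0) 0 else max(0, ctr - hw)
  hi <- if (k == n) 1 else min(1, ctr + hw)
  c(lo, hi)
}

derive_seed <- function(seed, i, salt = 0) {
  as.integer((as.numeric(seed) * 100003 + salt * 7919 + i) %% 2147483629)
}

#' Filter configuration for simulated data
#'
#' The default [filter_config()] includes the artifact-removal rule for
#' real alignments (allele-specific counts above 1000 are discarded as
#' likely mapping artifacts). Simulated reads contain no alignment
#' artifacts, and at high expression the rule would censor exactly the
#' high-count samples that carry the signal, so the evaluation suites
#' disable it while keeping the per-sample minimum-read rule.
#'
#' @param ... Overrides passed to [filter_config()].
#' @return A `filter_config` with `asc_outlier_max = Inf`.
#' @export
sim_filter_config <- function(...) {
  filter_config(asc_outlier_max = Inf, ...)
}

#' Type I error and power over a simulation grid
#'
#' For each grid cell, simulates `n_rep` single-candidate-variant replicate
#' genes and records the fraction of replicates rejected at `alpha` by the
#' combined test (`mixqtl`), the total-count-only test (`trcqtl`) and the
#' allelic-imbalance-only test (`ascqtl`). At `aFC = 1` the rejection rate
#' is the empirical type I error; otherwise it is power. Wilson 95%
#' binomial intervals accompany every estimate. Replicates where a
#' component's statistic is undefined (e.g. too few allele-specific
#' samples) are excluded from that component's denominator.
#'
#' @param grid A data frame with columns `n`, `theta`, `aFC` (one row per
#'   cell). Default: a reduced grid (`n` in \{100, 500\}, `theta` in
#'   \{5e-5, 1e-6\}, `aFC` in \{1, 1.25, 2\}).
#' @param alpha Nominal significance level (default 0.05).
#' @param n_rep Replicates per cell (default 200).
#' @param seed Integer seed.
#' @param cfg_args Extra arguments passed to [sim_config()].
#' @param filters A [filter_config]; defaults to [sim_filter_config()].
#' @return A tibble with `n`, `theta`, `aFC`, `method`, `metric`,
#'   `estimate`, `ci_lo`, `ci_hi`, `n_replicates`, `n_defined`.
#' @export
type1_power_suite <- function(grid = default_qtl_grid(), alpha = 0.05,
                              n_rep = 200, seed = 1, cfg_args = list(),
                              filters = sim_filter_config()) {
  grid <- tibble::as_tibble(grid)
  purrr::map_dfr(seq_len(nrow(grid)), function(g) {
    cell <- grid[g, ]
    ps <- purrr::map_dfr(seq_len(n_rep), function(i) {
      cfg <- do.call(sim_config, c(
        list(
          n_samples = cell$n, theta = cell$theta, aFC = cell$aFC,
          n_causal = 1, n_variants = 1,
          seed = derive_seed(seed, i, salt = g)
        ),
        cfg_args
      ))
      sim <- simulate_dataset(cfg)
      prep <- prepare_gene(sim$counts, filters)
      res <- run_cis_scan(prep, sim$geno, filters)
      tibble::tibble(
        mixqtl = res$p_meta[1], trcqtl = res$p_trc[1], ascqtl = res$p_asc[1]
      )
    })
    purrr::map_dfr(c("mixqtl", "trcqtl", "ascqtl"), function(m) {
      p <- ps[[m]]
      ok <- is.finite(p)
      k <- sum(p[ok] < alpha)
      ci <- wilson_ci(k, sum(ok))
      tibble::tibble(
        n = cell$n, theta = cell$theta, aFC = cell$aFC, method = m,
        metric = if (cell$aFC == 1) "type1_error" else "power",
        estimate = if (sum(ok) > 0) k / sum(ok) else NA_real_,
        ci_lo = ci[1], ci_hi = ci[2],
        n_replicates = n_rep, n_defined = sum(ok)
      )
    })
  })
}

#' @rdname type1_power_suite
#' @export
default_qtl_grid <- function() {
  tidyr::expand_grid(n = c(100, 500), theta = c(5e-5, 1e-6),
                     aFC = c(1, 1.25, 2))
}

#' Fine-mapping simulation suite
#'
#' Simulates `n_rep` replicate genes with causal signals (plus `n_null`
#' null replicates used for PIP calibration pooling), runs the combined
#' (`mixfine`) and total-count-only (`trcfine`) solvers on identical data
#' and collects per-replicate detections (causal variant PIP above
#' `pip_threshold`), credible-set sizes and coverage, and pooled PIPs.
#'
#' @param n_rep Number of signal replicates (default 20).
#' @param n_null Number of null replicates (default 0).
#' @param n_samples,theta,h2,n_causal,n_variants Simulation parameters
#'   passed to [sim_config()].
#' @param pip_threshold Detection threshold (default 0.5).
#' @param ld_rho Lag-1 latent LD parameter passed to [sim_config()]
#'   (default 0.9, emulating a cis-window haplotype panel; the original
#'   fine-mapping evaluation drew genotypes from a reference panel, and
#'   linkage is what spreads inclusion mass across credible-set members).
#' @param seed Integer seed.
#' @param ibss An [ibss_config].
#' @param cfg_args Extra [sim_config()] arguments.
#' @param filters A [filter_config]; defaults to [sim_filter_config()].
#' @return A list with `detail` (tibble: replicate, method, causal PIP
#'   summary, CS metrics), `pips` (tibble: method, pip, causal; pooled over
#'   all replicates), `report` (tibble of per-method summary metrics with
#'   Wilson CIs where binomial).
#' @export
finemap_suite <- function(n_rep = 20, n_null = 0, n_samples = 500,
                          theta = 5e-5, h2 = 0.4, n_causal = 1,
                          n_variants = 200, pip_threshold = 0.5,
                          ld_rho = 0.9, seed = 1,
                          ibss = ibss_config(), cfg_args = list(),
                          filters = sim_filter_config()) {
  run_one <- function(i, null_rep) {
    cfg <- do.call(sim_config, c(
      list(
        n_samples = n_samples, theta = theta,
        h2 = if (null_rep) NULL else h2, aFC = 1,
        n_causal = if (null_rep) 0 else n_causal, n_variants = n_variants,
        ld_rho = ld_rho,
        seed = derive_seed(seed, i, salt = if (null_rep) 2 else 1)
      ),
      cfg_args
    ))
    sim <- simulate_dataset(cfg)
    prep <- prepare_gene(sim$counts, filters)
    causal <- sim$truth$causal
    purrr::map_dfr(c("mixfine", "trcfine"), function(m) {
      fit <- if (m == "mixfine") {
        mixfine(prep, sim$geno, ibss)
      } else {
        trcfine(prep, sim$geno, ibss)
      }
      pip <- fit$pip$pip
      cs <- fit$credible_sets
      cs_hit <- vapply(cs$variants, function(v) any(v %in% causal), TRUE)
      tibble::tibble(
        replicate = i, null_rep = null_rep, method = m,
        n_causal = length(causal),
        n_detected = sum(pip[causal] > pip_threshold),
        n_false = sum(pip[setdiff(seq_along(pip), causal)] > pip_threshold),
        n_cs = nrow(cs),
        n_cs_hit = sum(cs_hit),
        mean_cs_size_hit = if (any(cs_hit)) mean(cs$size[cs_hit]) else NA_real_,
        pips = list(tibble::tibble(
          pip = pip, causal = seq_along(pip) %in% causal
        ))
      )
    })
  }
  detail <- dplyr::bind_rows(
    purrr::map_dfr(seq_len(n_rep), run_one, null_rep = FALSE),
    if (n_null > 0) purrr::map_dfr(seq_len(n_null), run_one, null_rep = TRUE)
  )
  pips <- tidyr::unnest(
    dplyr::select(detail, "method", "pips"), "pips"
  )
  detail$pips <- NULL
  report <- purrr::map_dfr(c("mixfine", "trcfine"), function(m) {
    d <- detail[detail$method == m & !detail$null_rep, ]
    det_ci <- wilson_ci(sum(d$n_detected), sum(d$n_causal))
    cov_ci <- wilson_ci(sum(d$n_cs_hit), max(sum(d$n_cs), 1))
    tibble::tibble(
      method = m,
      metric = c("detection_rate", "mean_cs_size", "cs_coverage"),
      estimate = c(
        sum(d$n_detected) / sum(d$n_causal),
        mean(d$mean_cs_size_hit, na.rm = TRUE),
        if (sum(d$n_cs) > 0) sum(d$n_cs_hit) / sum(d$n_cs) else NA_real_
      ),
      ci_lo = c(det_ci[1], NA, cov_ci[1]),
      ci_hi = c(det_ci[2], NA, cov_ci[2]),
      n_replicates = n_rep
    )
  })
  list(detail = detail, pips = pips, report = report)
}

#' Prediction simulation suite
#'
#' Simulates replicate genes, splits each into training (`split` fraction)
#' and test sets, trains the combined and total-count-only elastic-net
#' models on the training samples and reports the held-out Pearson
#' correlation with observed `log(total/(2*libsize))`. Each replicate's
#' split is repeated `repeats` times to damp splitting noise.
#'
#' @param n_rep Number of replicates (default 20).
#' @param n_samples,theta,h2,n_causal,n_variants [sim_config()] parameters.
#' @param split Training fraction (default 4/5).
#' @param repeats Split repetitions per replicate (default 2).
#' @param ld_rho Lag-1 latent LD parameter (default 0.9), as in
#'   [finemap_suite()]: prediction is evaluated on the same kind of
#'   linked-genotype data as fine-mapping.
#' @param seed Integer seed.
#' @param cfg_args Extra [sim_config()] arguments.
#' @param filters A [filter_config]; defaults to [sim_filter_config()].
#' @return A list with `detail` (tibble: replicate, repeat, method, r) and
#'   `report` (per-method mean r with normal-theory CI).
#' @export
prediction_suite <- function(n_rep = 20, n_samples = 500, theta = 5e-5,
                             h2 = 0.4, n_causal = 2, n_variants = 200,
                             split = 4 / 5, repeats = 2, ld_rho = 0.9,
                             seed = 1, cfg_args = list(),
                             filters = sim_filter_config()) {
  detail <- purrr::map_dfr(seq_len(n_rep), function(i) {
    cfg <- do.call(sim_config, c(
      list(
        n_samples = n_samples, theta = theta, h2 = h2, n_causal = n_causal,
        n_variants = n_variants, ld_rho = ld_rho,
        seed = derive_seed(seed, i, salt = 3)
      ),
      cfg_args
    ))
    sim <- simulate_dataset(cfg)
    purrr::map_dfr(seq_len(repeats), function(rep_i) {
      old <- local_seed(derive_seed(seed, i, salt = 30 + rep_i))
      idx <- sample.int(n_samples)
      restore_seed(old)
      n_train <- round(split * n_samples)
      res <- evaluate_split(
        sim$counts, sim$geno,
        train = idx[seq_len(n_train)], test = idx[-seq_len(n_train)],
        cfg = filters, covariates = NULL, alpha_mix = 0.5,
        fold = rep_i
      )
      dplyr::mutate(res, replicate = i, .before = 1)
    })
  })
  report <- detail |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      metric = "mean_pearson_r",
      estimate = mean(.data$r, na.rm = TRUE),
      ci_lo = .data$estimate - 1.96 * sd(.data$r, na.rm = TRUE) /
        sqrt(sum(is.finite(.data$r))),
      ci_hi = .data$estimate + 1.96 * sd(.data$r, na.rm = TRUE) /
        sqrt(sum(is.finite(.data$r))),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  list(detail = detail, report = report)
}
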