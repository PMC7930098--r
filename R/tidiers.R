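#' Tidy a fine-mapping fit
#'
#' @param x A `finemap_fit`.
#' @param ... Unused.
#' @return A tibble with one row per variant: `variant_id`, `pip`, `cs_id`
#'   (NA outside any credible set), `cs_size`, `purity`.
#' @export
tidy.finemap_fit <- function(x, ...) {
  out <- x$pip
  out$cs_id <- NA_integer_
  out$cs_size <- NA_integer_
  out$purity <- NA_real_
  cs <- x$credible_sets
  for (k in seq_len(nrow(cs))) {
    idx <- cs$variants[[k]]
    out$cs_id[idx] <- cs$cs_id[k]
    out$cs_size[idx] <- cs$size[k]
    out$purity[idx] <- cs$purity[k]
  }
  out
}

#' @rdname tidy.finemap_fit
#' @export
glance.finemap_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, p = x$p, n_effects_used = x$n_effects_used,
    n_credible_sets = nrow(x$credible_sets),
    sigma2 = x$sigma2,
    elbo = x$elbo[length(x$elbo)],
    n_iter = length(x$elbo),
    converged = x$converged
  )
}

#' Tidy a prediction model
#'
#' @param x A `mixpred_model`.
#' @param ... Unused.
#' @return The per-variant weight tibble (per-allele log fold-change
#'   scale).
#' @export
tidy.mixpred_model <- function(x, ...) {
  x$weights
}

#' @rdname tidy.mixpred_model
#' @export
glance.mixpred_model <- function(x, ...) {
  tibble::tibble(
    n_variants = nrow(x$weights),
    n_nonzero = sum(x$weights$weight != 0),
    intercept = x$intercept,
    lambda = x$lambda,
    alpha_mix = x$alpha_mix
  )
}
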