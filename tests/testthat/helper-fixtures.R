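# Fixture builders: everything is generated in code at test time.

write_fixture_vcf <- function(path, records,
                              samples = c("S1", "S2", "S3")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, id, gts, ref = "A", alt = "G") {
  paste(c(chrom, pos, id, ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

# small deterministic genotype container
toy_genotypes <- function(n = 6, pos = c(100L, 200L, 300L), seed = 1) {
  set.seed(seed)
  p <- length(pos)
  phased_genotypes(
    tibble::tibble(variant_id = paste0("v", seq_len(p)), chrom = "1",
                   pos = pos),
    matrix(rbinom(n * p, 1, 0.4), n, p),
    matrix(rbinom(n * p, 1, 0.4), n, p)
  )
}

toy_counts <- function(n = 6, seed = 1) {
  set.seed(seed)
  total <- rpois(n, 500)
  asc1 <- rbinom(n, total %/% 2, 0.5)
  asc2 <- rbinom(n, total %/% 2, 0.5)
  gene_counts(total, asc1, asc2, libsize = rep(1e6, n))
}

# closed-form OLS slope/se oracle (simple regression with intercept)
ols_oracle <- function(y, x) {
  n <- length(y)
  xc <- x - mean(x); yc <- y - mean(y)
  beta <- sum(xc * yc) / sum(xc^2)
  r <- yc - beta * xc
  se <- sqrt(sum(r^2) / (n - 2) / sum(xc^2))
  list(beta = beta, se = se)
}

# generalized least squares through the origin with V = diag(1/w)
gls_oracle <- function(y, x, w) {
  Vinv <- diag(w)
  X <- matrix(x, ncol = 1)
  beta <- solve(t(X) %*% Vinv %*% X, t(X) %*% Vinv %*% y)
  r <- y - X %*% beta
  n <- length(y)
  s2 <- drop(t(r) %*% Vinv %*% r) / (n - 1)
  se <- sqrt(s2 * solve(t(X) %*% Vinv %*% X))
  list(beta = drop(beta), se = drop(se))
}

# independent log Bayes factor via the marginal likelihood (Woodbury form)
lbf_oracle <- function(y, x, v0, sigma2 = 1) {
  xtx <- sum(x^2)
  xty <- sum(x * y)
  -0.5 * log(1 + v0 * xtx / sigma2) +
    0.5 * v0 * xty^2 / (sigma2 * (sigma2 + v0 * xtx))
}
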