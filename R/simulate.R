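#' Simulation configuration
#'
#' Defaults describe a GTEx-like bulk RNA-seq study: 500 samples with
#' negative-binomial library sizes averaging 94 million reads, a gene whose
#' baseline relative abundance `theta_0,i` is Beta-distributed around
#' `theta` (50 reads per million at the default 5e-5), about 10 polymorphic
#' readout sites uniformly placed on a 2 kb gene body read with 76 bp
#' single-end reads, and candidate variants with minor allele frequencies
#' drawn uniformly from `[0.05, 0.3]`.
#'
#' The baseline abundance is parameterized as
#' `theta_0,i = 2 * theta * B_i`, `B_i ~ Beta(beta_conc, beta_conc)`, a
#' Beta-distributed abundance with mean `theta` and mild log-scale spread
#' (about 0.16 sd at the default concentration 20); parameterizing a Beta
#' directly by mean 5e-5 would produce a degenerate, essentially
#' zero-inflated baseline.
#'
#' Genetic effects: with `h2 = NULL`, each causal variant gets
#' `beta = log(aFC)` (recycled). With `h2` set, effect sizes are drawn
#' `N(0, 1)` and rescaled so the genetic variance of the average-dosage
#' score is `h2 / (1 - h2)` times the non-genetic log-expression variance
#' `var(log theta_0) + nb_disp/(2 * mean_libsize * theta)` (baseline
#' spread plus count noise), making `h2` the fraction of log total-count
#' variance explained by the causal variants.
#'
#' @param n_samples Number of individuals (default 500).
#' @param mean_libsize Mean library size (default 94e6).
#' @param libsize_size Negative-binomial size for library sizes (default 10).
#' @param theta Expected baseline relative abundance (default 5e-5).
#' @param beta_conc Beta concentration for the baseline abundance
#'   (default 20).
#' @param aFC Allelic fold change(s) of the causal variant(s) (default 1.5);
#'   used when `h2` is NULL.
#' @param n_causal Number of causal variants (default 1).
#' @param h2 Target cis-heritability of log expression, or NULL.
#' @param n_variants Number of candidate variants simulated (default
#'   `n_causal`).
#' @param n_sites Expected number of polymorphic readout sites, Poisson
#'   (default 10).
#' @param maf Minor-allele-frequency range (default `c(0.05, 0.3)`).
#' @param gene_length Gene-body length in bp (default 2000).
#' @param read_length Read length in bp (default 76).
#' @param nb_disp Overdispersion factor for haplotypic counts (default
#'   1.5): counts are negative binomial with `Var = nb_disp * mean`
#'   (quasi-Poisson/NB1 regime, so the count variance stays proportional
#'   to the count as the model assumes); 1 gives Poisson counts.
#' @param ld_panel Optional haplotype panel (matrix, haplotypes x variants,
#'   0/1): individuals are formed by drawing pairs of panel haplotypes,
#'   preserving the panel's LD, instead of independent Bernoulli sites.
#' @param ld_rho Optional lag-1 latent correlation in `(0, 1)`: haplotypes
#'   are generated by thresholding an AR(1) Gaussian process at the
#'   per-site allele frequency, giving linkage disequilibrium that decays
#'   with variant distance (a synthetic stand-in for a reference haplotype
#'   panel). `NULL` (default) gives independent sites; ignored when
#'   `ld_panel` is supplied.
#' @param seed Integer seed (default 1).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 500, mean_libsize = 94e6,
                       libsize_size = 10, theta = 5e-5, beta_conc = 20,
                       aFC = 1.5, n_causal = 1, h2 = NULL,
                       n_variants = n_causal, n_sites = 10,
                       maf = c(0.05, 0.3), gene_length = 2000,
                       read_length = 76, nb_disp = 1.5, ld_panel = NULL,
                       ld_rho = NULL, seed = 1) {
  stopifnot(
    n_samples > 0, mean_libsize > 0, theta > 0, beta_conc > 0,
    all(aFC > 0), n_causal >= 0, n_variants >= n_causal,
    length(maf) == 2, all(maf > 0), all(maf <= 0.5),
    gene_length > read_length, nb_disp >= 1, libsize_size > 0
  )
  if (!is.null(h2)) stopifnot(h2 > 0, h2 < 1)
  if (!is.null(ld_rho)) stopifnot(ld_rho > 0, ld_rho < 1)
  structure(
    list(
      n_samples = n_samples, mean_libsize = mean_libsize,
      libsize_size = libsize_size, theta = theta, beta_conc = beta_conc,
      aFC = aFC, n_causal = n_causal, h2 = h2, n_variants = n_variants,
      n_sites = n_sites, maf = maf, gene_length = gene_length,
      read_length = read_length, nb_disp = nb_disp, ld_panel = ld_panel,
      ld_rho = ld_rho, seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate a gene-body readout configuration
#'
#' Draws the polymorphic readout sites (count Poisson around `n_sites`,
#' positions uniform over the gene body, per-site allele frequency uniform
#' over the MAF range) and, per individual, independent haplotype alleles
#' `Bernoulli(f)` at each site, so a site is heterozygous with probability
#' `2 f (1 - f)`.
#'
#' @param cfg A [sim_config].
#' @return A list `site_pos` (integer bp), `site_f`, `het` (samples x sites
#'   logical matrix).
#' @export
simulate_gene_config <- function(cfg) {
  s <- rpois(1, cfg$n_sites)
  pos <- sort(ceiling(runif(s, 0, cfg$gene_length)))
  f <- runif(s, cfg$maf[1], cfg$maf[2])
  het <- matrix(FALSE, cfg$n_samples, s)
  for (k in seq_len(s)) {
    a1 <- rbinom(cfg$n_samples, 1, f[k])
    a2 <- rbinom(cfg$n_samples, 1, f[k])
    het[, k] <- a1 != a2
  }
  list(site_pos = pos, site_f = f, het = het)
}

# one haplotype set from the AR(1) latent-Gaussian LD model
ar1_haplotypes <- function(n, thr, rho) {
  p <- length(thr)
  Z <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(p)[-1]) {
    Z[, j] <- rho * Z[, j - 1] + sqrt(1 - rho^2) * Z[, j]
  }
  (Z < matrix(thr, n, p, byrow = TRUE)) + 0
}

# simulate candidate phased genotypes (independent sites, AR(1) LD, or
# external LD panel draws)
simulate_genotypes <- function(cfg) {
  n <- cfg$n_samples
  p <- cfg$n_variants
  if (!is.null(cfg$ld_panel)) {
    H <- as.matrix(cfg$ld_panel)
    stopifnot(ncol(H) >= p)
    H <- H[, seq_len(p), drop = FALSE]
    i1 <- sample.int(nrow(H), n, replace = TRUE)
    i2 <- sample.int(nrow(H), n, replace = TRUE)
    hap1 <- H[i1, , drop = FALSE]
    hap2 <- H[i2, , drop = FALSE]
  } else if (!is.null(cfg$ld_rho)) {
    f <- runif(p, cfg$maf[1], cfg$maf[2])
    thr <- qnorm(f)
    hap1 <- ar1_haplotypes(n, thr, cfg$ld_rho)
    hap2 <- ar1_haplotypes(n, thr, cfg$ld_rho)
  } else {
    f <- runif(p, cfg$maf[1], cfg$maf[2])
    hap1 <- matrix(rbinom(n * p, 1, rep(f, each = n)), n, p)
    hap2 <- matrix(rbinom(n * p, 1, rep(f, each = n)), n, p)
  }
  pos <- sort(sample.int(2e6, p))
  phased_genotypes(
    tibble::tibble(
      variant_id = paste0("v", seq_len(p)), chrom = "1", pos = pos
    ),
    hap1, hap2
  )
}

# log-scale non-genetic variance of the total-count response implied by cfg
sim_noise_variance <- function(cfg) {
  var_log_theta0 <- trigamma(cfg$beta_conc) - trigamma(2 * cfg$beta_conc)
  var_log_theta0 + cfg$nb_disp / (2 * cfg$mean_libsize * cfg$theta)
}

# draw causal effects; returns list(beta = length-p vector, causal = indices)
draw_effects <- function(cfg, geno) {
  p <- cfg$n_variants
  beta <- numeric(p)
  causal <- integer(0)
  if (cfg$n_causal > 0) {
    causal <- sort(sample.int(p, cfg$n_causal))
    if (is.null(cfg$h2)) {
      beta[causal] <- log(rep_len(cfg$aFC, cfg$n_causal))
    } else {
      b <- rnorm(cfg$n_causal)
      xbar <- (geno$hap1[, causal, drop = FALSE] +
                 geno$hap2[, causal, drop = FALSE]) / 2
      vg <- var(drop(xbar %*% b))
      if (vg <= 0) vg <- 1e-12
      target <- cfg$h2 / (1 - cfg$h2) * sim_noise_variance(cfg)
      beta[causal] <- b * sqrt(target / vg)
    }
  }
  list(beta = beta, causal = causal)
}

#' Simulate haplotypic counts given genotypes and effects
#'
#' Library sizes are negative binomial around `mean_libsize`; the baseline
#' abundance `theta_0,i` is Beta-distributed around `theta`; each
#' haplotype's abundance is `theta_0,i * exp(sum_j beta_j X^h_ij)`
#' (allelic fold change `e^beta` per alternative allele) and its read count
#' negative binomial with that expected count and variance
#' `nb_disp * mean`.
#'
#' @param cfg A [sim_config].
#' @param geno A [phased_genotypes] for the candidate variants.
#' @param beta Per-variant effect vector (length `n_variants`).
#' @return A list `y1`, `y2` (haplotypic counts), `libsize`, `theta0`.
#' @export
simulate_counts <- function(cfg, geno, beta) {
  n <- cfg$n_samples
  L <- rnbinom(n, mu = cfg$mean_libsize, size = cfg$libsize_size)
  L <- pmax(L, 1)
  theta0 <- 2 * cfg$theta * rbeta(n, cfg$beta_conc, cfg$beta_conc)
  g1 <- drop(geno$hap1 %*% beta)
  g2 <- drop(geno$hap2 %*% beta)
  m1 <- L * theta0 * exp(g1)
  m2 <- L * theta0 * exp(g2)
  draw_nb1 <- function(m) {
    if (cfg$nb_disp == 1) return(rpois(n, m))
    rnbinom(n, mu = m, size = m / (cfg$nb_disp - 1))
  }
  y1 <- draw_nb1(m1)
  y2 <- draw_nb1(m2)
  list(y1 = y1, y2 = y2, libsize = L, theta0 = theta0)
}

# exact probability that a uniformly placed read overlaps >= 1 het site
asc_fraction <- function(site_pos, gene_length, read_length) {
  n_starts <- gene_length - read_length + 1
  if (length(site_pos) == 0) return(0)
  lo <- pmax(site_pos - read_length + 1, 1)
  hi <- pmin(site_pos, n_starts)
  keep <- lo <= hi
  lo <- lo[keep]; hi <- hi[keep]
  if (length(lo) == 0) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  covered <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] > cur_hi + 1) {
      covered <- covered + cur_hi - cur_lo + 1
      cur_lo <- lo[k]; cur_hi <- hi[k]
    } else {
      cur_hi <- max(cur_hi, hi[k])
    }
  }
  covered <- covered + cur_hi - cur_lo + 1
  covered / n_starts
}

#' Read out allele-specific counts
#'
#' Each of the `Y^h` haplotypic reads starts uniformly on the gene body and
#' is allele-specific iff it overlaps at least one heterozygous site; the
#' per-read probability is computed exactly from the union of the het-site
#' windows and the allele-specific count drawn binomially (distributionally
#' identical to placing reads one by one). The observed total count is the
#' sum of the two haplotypic counts regardless of het sites.
#'
#' @param y1,y2 Haplotypic read counts.
#' @param het Samples x sites logical matrix of heterozygosity.
#' @param site_pos Site positions (bp).
#' @param cfg A [sim_config].
#' @return A list `asc1`, `asc2`, `total`, `alpha` (per-sample asc
#'   fraction).
#' @export
readout_asc <- function(y1, y2, het, site_pos, cfg) {
  n <- length(y1)
  alpha <- vapply(seq_len(n), function(i) {
    asc_fraction(site_pos[het[i, ]], cfg$gene_length, cfg$read_length)
  }, numeric(1))
  asc1 <- rbinom(n, y1, alpha)
  asc2 <- rbinom(n, y2, alpha)
  list(asc1 = asc1, asc2 = asc2, total = y1 + y2, alpha = alpha)
}

#' Simulate a full gene dataset
#'
#' Composes the three steps: gene-body configuration (het readout sites),
#' haplotypic count generation, and allele-specific readout. Reproducible
#' given `cfg$seed`.
#'
#' @param cfg A [sim_config].
#' @return A `simulated_dataset` list: `geno` ([phased_genotypes] with a
#'   `causal` flag column in `$variants`), `counts` ([gene_counts]),
#'   `truth` (list `beta`, `causal`, `theta0`, `alpha`, `libsize`, `y1`,
#'   `y2`), `cfg`.
#' @export
simulate_dataset <- function(cfg) {
  old <- local_seed(cfg$seed)
  on.exit(restore_seed(old))
  gc_ <- simulate_gene_config(cfg)
  geno <- simulate_genotypes(cfg)
  eff <- draw_effects(cfg, geno)
  cnt <- simulate_counts(cfg, geno, eff$beta)
  ro <- readout_asc(cnt$y1, cnt$y2, gc_$het, gc_$site_pos, cfg)
  geno$variants$causal <- seq_len(cfg$n_variants) %in% eff$causal
  counts <- gene_counts(ro$total, ro$asc1, ro$asc2, cnt$libsize)
  structure(
    list(
      geno = geno, counts = counts,
      truth = list(
        beta = eff$beta, causal = eff$causal, theta0 = cnt$theta0,
        alpha = ro$alpha, libsize = cnt$libsize, y1 = cnt$y1, y2 = cnt$y2
      ),
      cfg = cfg
    ),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> n=%d, %d variant(s), %d causal, mean total count %.0f\n",
    x$cfg$n_samples, x$cfg$n_variants, length(x$truth$causal),
    mean(x$counts$total)
  ))
  invisible(x)
}

#' Write a simulated dataset in the analysis input formats
#'
#' Emits the same TSV/VCF formats the scan consumes: a phased VCF, the four
#' count/libsize tables and a gene annotation table, so simulator output
#' feeds straight back into [read_phased_vcf()] / [read_count_tables()].
#'
#' @param sim A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @param gene_id Gene identifier used in the tables (default "geneSim").
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir, gene_id = "geneSim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- paste0("S", seq_len(sim$cfg$n_samples))
  v <- sim$geno$variants
  gt <- vapply(seq_len(nrow(v)), function(j) {
    paste0(sim$geno$hap1[, j], "|", sim$geno$hap2[, j])
  }, character(sim$cfg$n_samples))
  gt <- matrix(gt, nrow = sim$cfg$n_samples)
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(j) {
      paste(c(v$chrom[j], v$pos[j], v$variant_id[j], "A", "G", ".", "PASS",
              ".", "GT", gt[, j]), collapse = "\t")
    }, character(1))
  )
  writeLines(vcf_lines, file.path(dir, "genotypes.vcf"))
  write_counts <- function(x, name) {
    d <- tibble::as_tibble(as.list(setNames(x, samples)))
    d <- dplyr::mutate(d, gene_id = gene_id, .before = 1)
    readr::write_tsv(d, file.path(dir, name), progress = FALSE)
  }
  write_counts(sim$counts$total, "total.tsv")
  write_counts(sim$counts$asc1, "asc1.tsv")
  write_counts(sim$counts$asc2, "asc2.tsv")
  readr::write_tsv(
    tibble::tibble(sample_id = samples, libsize = sim$counts$libsize),
    file.path(dir, "libsize.tsv"), progress = FALSE
  )
  readr::write_tsv(
    tibble::tibble(gene_id = gene_id, chrom = v$chrom[1],
                   tss = as.integer(median(v$pos)), strand = "+"),
    file.path(dir, "annotation.tsv"), progress = FALSE
  )
  invisible(dir)
}
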