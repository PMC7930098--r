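test_that("heterozygosity rate follows 2f(1-f)", {
  set.seed(81)
  cfg <- sim_config(n_samples = 4000, n_sites = 12, maf = c(0.1, 0.1))
  gc_ <- simulate_gene_config(cfg)
  expect_equal(mean(gc_$het), 2 * 0.1 * 0.9, tolerance = 0.02)
  cfg5 <- sim_config(n_samples = 4000, n_sites = 12, maf = c(0.5, 0.5))
  gc5 <- simulate_gene_config(cfg5)
  expect_equal(mean(gc5$het), 0.5, tolerance = 0.02)
})

test_that("haplotypic counts have the configured mean and aFC ratio", {
  set.seed(82)
  n <- 20000
  cfg <- sim_config(n_samples = n, mean_libsize = 1e6, libsize_size = 1e9,
                    theta = 5e-5, beta_conc = 1e6, nb_disp = 1.5,
                    n_variants = 1)
  geno <- phased_genotypes(
    tibble::tibble(variant_id = "v1", chrom = "1", pos = 1L),
    hap1 = matrix(1, n, 1), hap2 = matrix(0, n, 1)
  )
  cnt <- simulate_counts(cfg, geno, beta = log(2))
  # alt haplotype doubled; ref at L * theta = 50
  expect_equal(mean(cnt$y2), 50, tolerance = 0.05 * 50)
  expect_equal(mean(cnt$y1) / mean(cnt$y2), 2, tolerance = 0.05)
  # count variance scales linearly with the count: var/mean ~ nb_disp
  cnt0 <- simulate_counts(cfg, geno, beta = 0)
  vm <- var(cnt0$y2) / mean(cnt0$y2)
  expect_equal(vm, 1.5, tolerance = 0.1)
})

test_that("asc fraction is the exact read-window coverage probability", {
  # one interior het site, gene 2000, read 76: 76/1925 eligible starts
  expect_equal(asc_fraction(1000L, 2000, 76), 76 / (2000 - 76 + 1),
               tolerance = 1e-12)
  # no het sites
  expect_equal(asc_fraction(integer(0), 2000, 76), 0)
  # het site at every bp saturates
  expect_equal(asc_fraction(1:2000, 2000, 76), 1)
  # overlapping windows are not double counted
  expect_lt(asc_fraction(c(1000L, 1010L), 2000, 76), 2 * 76 / 1925)

  # empirical check by brute-force read placement
  set.seed(83)
  sites <- c(300L, 1200L, 1210L)
  p <- asc_fraction(sites, 2000, 76)
  starts <- sample.int(2000 - 76 + 1, 1e5, replace = TRUE)
  hit <- vapply(starts, function(s) any(sites >= s & sites < s + 76), TRUE)
  expect_lt(abs(mean(hit) - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("readout obeys saturation and degenerate limits", {
  set.seed(84)
  cfg <- sim_config(n_samples = 5)
  y1 <- c(100L, 50L, 80L, 10L, 0L)
  y2 <- c(90L, 60L, 70L, 20L, 5L)
  # every bp heterozygous: all reads allele-specific
  het_all <- matrix(TRUE, 5, cfg$gene_length)
  ro <- readout_asc(y1, y2, het_all, seq_len(cfg$gene_length), cfg)
  expect_equal(ro$asc1, y1)
  expect_equal(ro$asc2, y2)
  expect_equal(ro$total, y1 + y2)
  # no het sites: nothing allele-specific
  het_none <- matrix(FALSE, 5, 0)
  ro0 <- readout_asc(y1, y2, het_none, integer(0), cfg)
  expect_true(all(ro0$asc1 == 0) && all(ro0$asc2 == 0))
})

test_that("simulate_dataset is reproducible and respects invariants", {
  cfg <- sim_config(n_samples = 120, aFC = 1.5, n_variants = 8, seed = 85)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts$total, b$counts$total)
  expect_identical(a$geno$hap1, b$geno$hap1)
  expect_identical(a$truth$beta, b$truth$beta)
  # invariants
  expect_true(all(a$counts$asc1 + a$counts$asc2 <= a$counts$total))
  expect_true(all(a$counts$total >= 0))
  expect_equal(sum(a$geno$variants$causal), 1)
  # a different seed changes the data
  c2 <- simulate_dataset(sim_config(n_samples = 120, aFC = 1.5,
                                    n_variants = 8, seed = 86))
  expect_false(identical(a$counts$total, c2$counts$total))
})

test_that("library sizes average to the configured mean", {
  set.seed(87)
  L <- rnbinom(1e4, mu = 94e6, size = 10)
  expect_lt(abs(mean(L) / 94e6 - 1), 0.02)
})

test_that("h2 scaling yields the target fraction of log-expression variance", {
  r2 <- sapply(1:10, function(i) {
    sim <- simulate_dataset(sim_config(
      n_samples = 800, theta = 5e-5, h2 = 0.4, n_causal = 2, n_variants = 20,
      seed = 880 + i
    ))
    y <- log(pmax(sim$counts$total, 1) / (2 * sim$counts$libsize))
    xbar <- (sim$geno$hap1 + sim$geno$hap2) / 2
    g <- drop(xbar %*% sim$truth$beta)
    summary(lm(y ~ g))$r.squared
  })
  expect_equal(median(r2), 0.4, tolerance = 0.12)
})

test_that("LD panel mode draws haplotypes from the panel", {
  set.seed(88)
  H <- matrix(rbinom(40 * 6, 1, 0.3), 40, 6)
  sim <- simulate_dataset(sim_config(
    n_samples = 50, n_variants = 6, ld_panel = H, seed = 89
  ))
  # every individual haplotype must be a panel row
  key <- apply(H, 1, paste, collapse = "")
  expect_true(all(apply(sim$geno$hap1, 1, paste, collapse = "") %in% key))
})

test_that("simulator output round-trips through the file readers", {
  sim <- simulate_dataset(sim_config(n_samples = 25, n_variants = 4,
                                     aFC = 2, seed = 90))
  d <- withr::local_tempdir()
  write_simulated_dataset(sim, d)
  geno <- read_phased_vcf(file.path(d, "genotypes.vcf"))
  expect_equal(unname(geno$hap1), unname(sim$geno$hap1))
  expect_equal(unname(geno$hap2), unname(sim$geno$hap2))
  cnt <- read_count_tables(
    file.path(d, "total.tsv"), file.path(d, "asc1.tsv"),
    file.path(d, "asc2.tsv"), file.path(d, "libsize.tsv")
  )
  expect_equal(unname(cnt$geneSim$total), sim$counts$total)
  expect_equal(unname(cnt$geneSim$asc1), sim$counts$asc1)
  ann <- read_gene_annotation(file.path(d, "annotation.tsv"))
  expect_equal(ann$gene_id, "geneSim")
})
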