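#' Construct a phased-genotype container
#'
#' Holds per-variant haplotype allele dosages for a set of samples. Dosages
#' are 0/1 (biallelic, phased); `NA` marks missing genotypes.
#'
#' @param variants A data frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based coordinates).
#' @param hap1,hap2 Numeric matrices, samples x variants, entries in
#'   \{0, 1, NA\}. Column order must match `variants$variant_id`; rownames
#'   are sample IDs.
#'
#' @return An object of class `phased_genotypes`: a list with elements
#'   `variants` (tibble) and `hap1`/`hap2` (matrices).
#' @export
phased_genotypes <- function(variants, hap1, hap2) {
  variants <- tibble::as_tibble(variants)
  stopifnot(
    all(c("variant_id", "chrom", "pos") %in% names(variants)),
    is.matrix(hap1), is.matrix(hap2),
    identical(dim(hap1), dim(hap2)),
    ncol(hap1) == nrow(variants)
  )
  if (anyDuplicated(variants$variant_id)) {
    abort("duplicate variant_id in phased genotypes")
  }
  if (!all(is.na(c(hap1, hap2)) | c(hap1, hap2) %in% c(0, 1))) {
    abort("haplotype dosages must be 0, 1 or NA")
  }
  colnames(hap1) <- colnames(hap2) <- variants$variant_id
  structure(
    list(variants = variants, hap1 = hap1, hap2 = hap2),
    class = "phased_genotypes"
  )
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat(sprintf(
    "<phased_genotypes> %d samples x %d variants\n",
    nrow(x$hap1), ncol(x$hap1)
  ))
  print(head(x$variants, 5))
  invisible(x)
}

#' @export
dim.phased_genotypes <- function(x) dim(x$hap1)

n_samples <- function(geno) nrow(geno$hap1)
n_variants <- function(geno) ncol(geno$hap1)

#' Read phased genotypes from a VCF file
#'
#' Parses phased GT fields (`0|1` style) of biallelic SNVs into haplotype
#' dosage matrices. Unphased (`/`-separated) and multiallelic records are
#' skipped; the number skipped is reported via a message and stored in the
#' `n_skipped` attribute.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param region Optional `"chrom:start-end"` string restricting the variants
#'   returned (1-based, inclusive).
#'
#' @return A [phased_genotypes] object. Missing genotypes (`.|.`) become `NA`.
#' @export
read_phased_vcf <- function(path, region = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcf@fix, stringsAsFactors = FALSE))
  if (nrow(fix) == 0) {
    empty <- matrix(numeric(0), nrow = 0, ncol = 0)
    return(phased_genotypes(
      tibble::tibble(variant_id = character(), chrom = character(), pos = integer()),
      empty, empty
    ))
  }
  fmt <- if ("FORMAT" %in% colnames(vcf@gt)) vcf@gt[, "FORMAT"] else NULL
  if (is.null(fmt) || !all(vapply(strsplit(fmt, ":"), function(f) "GT" %in% f, TRUE))) {
    abort("VCF has no GT format field")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))

  pos <- as.integer(fix$POS)
  keep <- rep(TRUE, nrow(fix))
  # multiallelic: ALT contains a comma
  keep[grepl(",", fix$ALT)] <- FALSE
  # unphased or half-missing separators
  phased <- apply(gt, 1, function(g) all(is.na(g) | grepl("^[01.]\\|[01.]$", g)))
  keep <- keep & phased
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    inform(sprintf("read_phased_vcf: skipped %d unphased/multiallelic record(s)", n_skipped))
  }
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) != 4) abort("region must be 'chrom:start-end'")
    keep <- keep & fix$CHROM == m[2] &
      pos >= as.integer(m[3]) & pos <= as.integer(m[4])
  }

  idx <- which(keep)
  samples <- colnames(gt)
  parse_side <- function(g, side) {
    out <- suppressWarnings(as.numeric(vapply(
      strsplit(g, "|", fixed = TRUE),
      function(p) if (length(p) == 2) p[side] else NA_character_,
      character(1)
    )))
    out
  }
  hap1 <- matrix(NA_real_, nrow = length(samples), ncol = length(idx),
                 dimnames = list(samples, NULL))
  hap2 <- hap1
  for (k in seq_along(idx)) {
    g <- gt[idx[k], ]
    hap1[, k] <- parse_side(g, 1L)
    hap2[, k] <- parse_side(g, 2L)
  }
  ids <- fix$ID[idx]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[idx][no_id], ":", pos[idx][no_id])
  out <- phased_genotypes(
    tibble::tibble(variant_id = ids, chrom = fix$CHROM[idx], pos = pos[idx]),
    hap1, hap2
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Subset genotypes to the cis-window of a gene
#'
#' Keeps variants within `window` bp of the transcription start site,
#' inclusive on both ends. The window is symmetric around the TSS regardless
#' of strand.
#'
#' @param ann A one-row data frame with columns `gene_id`, `chrom`, `tss`
#'   (and optionally `strand`).
#' @param geno A [phased_genotypes] object.
#' @param window Window half-width in bp (default 1e6).
#'
#' @return A [phased_genotypes] object restricted to the window.
#' @export
cis_window <- function(ann, geno, window = 1e6) {
  stopifnot(window >= 0, nrow(ann) == 1)
  keep <- geno$variants$chrom == ann$chrom &
    geno$variants$pos >= ann$tss - window &
    geno$variants$pos <= ann$tss + window
  subset_variants(geno, keep)
}

subset_variants <- function(geno, keep) {
  phased_genotypes(
    geno$variants[keep, , drop = FALSE],
    geno$hap1[, keep, drop = FALSE],
    geno$hap2[, keep, drop = FALSE]
  )
}

subset_samples <- function(geno, idx) {
  phased_genotypes(
    geno$variants,
    geno$hap1[idx, , drop = FALSE],
    geno$hap2[idx, , drop = FALSE]
  )
}

#' Read gene-level count tables and library sizes
#'
#' Reads the total-count, haplotype-1 and haplotype-2 allele-specific count
#' matrices (TSV, genes x samples, first column `gene_id`) and a per-sample
#' library-size table (columns `sample_id`, `libsize`). Sample columns are
#' aligned by ID across all tables (intersection, with a warning when a table
#' lacks samples present elsewhere); genes present in the total table but
#' missing from the asc tables get zero allele-specific counts.
#'
#' @param total_path,asc1_path,asc2_path,libsize_path File paths.
#'
#' @return A named list of gene entries, each a list with `total`, `asc1`,
#'   `asc2` (integer vectors, named by sample) and `libsize`; plus an
#'   attribute `samples` with the common sample IDs.
#' @export
read_count_tables <- function(total_path, asc1_path, asc2_path, libsize_path) {
  read_mat <- function(p) {
    d <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- as.character(d[[1]])
    storage.mode(m) <- "double"
    if (any(m < 0, na.rm = TRUE)) abort(sprintf("negative count in %s", p))
    m
  }
  total <- read_mat(total_path)
  asc1 <- read_mat(asc1_path)
  asc2 <- read_mat(asc2_path)
  lib <- readr::read_tsv(libsize_path, show_col_types = FALSE, progress = FALSE)
  names(lib)[1:2] <- c("sample_id", "libsize")
  if (any(lib$libsize <= 0)) abort("library sizes must be positive")

  samples <- Reduce(intersect, list(
    colnames(total), colnames(asc1), colnames(asc2), lib$sample_id
  ))
  if (length(samples) == 0) {
    abort(paste0(
      "no common samples across tables; offenders include: ",
      paste(head(unique(c(colnames(total), lib$sample_id)), 10), collapse = ", ")
    ))
  }
  all_samp <- unique(c(colnames(total), colnames(asc1), colnames(asc2), lib$sample_id))
  if (length(samples) < length(all_samp)) {
    warn(sprintf(
      "sample tables aligned on %d common samples (%d dropped)",
      length(samples), length(all_samp) - length(samples)
    ))
  }
  libsize <- setNames(lib$libsize[match(samples, lib$sample_id)], samples)
  zero <- setNames(rep(0, length(samples)), samples)
  out <- lapply(rownames(total), function(g) {
    gene_counts(
      total = total[g, samples],
      asc1 = if (g %in% rownames(asc1)) asc1[g, samples] else zero,
      asc2 = if (g %in% rownames(asc2)) asc2[g, samples] else zero,
      libsize = libsize
    )
  })
  names(out) <- rownames(total)
  attr(out, "samples") <- samples
  out
}

#' Bundle per-gene counts
#'
#' @param total,asc1,asc2 Non-negative integer count vectors (one per sample).
#' @param libsize Positive per-sample library sizes.
#' @return A `gene_counts` list. If `asc1 + asc2 > total` for some sample a
#'   warning is issued (real pipelines can violate the inequality).
#' @export
gene_counts <- function(total, asc1, asc2, libsize) {
  n <- length(total)
  stopifnot(length(asc1) == n, length(asc2) == n, length(libsize) == n)
  if (any(total < 0) || any(asc1 < 0) || any(asc2 < 0)) {
    abort("counts must be non-negative")
  }
  if (any(libsize <= 0)) abort("library sizes must be positive")
  if (any(asc1 + asc2 > total)) {
    warn("asc1 + asc2 exceeds total for some samples")
  }
  structure(
    list(total = total, asc1 = asc1, asc2 = asc2, libsize = libsize),
    class = "gene_counts"
  )
}

#' Read a gene annotation table
#'
#' TSV with columns `gene_id`, `chrom`, `tss`, `strand`. BED input
#' (0-based starts) is converted to 1-based TSS on read when the file
#' extension is `.bed`.
#'
#' @param path File path.
#' @return A tibble with one row per gene.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.bed(\\.gz)?$", path)) {
    d <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene_id", "score", "strand"),
                         show_col_types = FALSE, progress = FALSE)
    ann <- tibble::tibble(
      gene_id = d$gene_id, chrom = d$chrom,
      tss = ifelse(d$strand == "-", d$end, d$start + 1L),
      strand = d$strand
    )
  } else {
    ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
  if (anyDuplicated(ann$gene_id)) abort("duplicate gene_id in annotation")
  if (any(ann$tss < 1)) abort("tss must be >= 1")
  tibble::as_tibble(ann)
}

#' Write association results to TSV
#'
#' @param results A tibble of association results (as returned by
#'   [run_cis_scan()] or [mixqtl_scan()]).
#' @param path Output path.
#' @return `results`, invisibly.
#' @export
write_assoc <- function(results, path) {
  cols <- c(
    "gene_id", "variant_id", "n_trc", "n_asc",
    "beta_trc", "se_trc", "p_trc",
    "beta_asc", "se_asc", "p_asc",
    "beta_meta", "se_meta", "p_meta", "method"
  )
  out <- tibble::as_tibble(results)
  for (cl in setdiff(cols, names(out))) out[[cl]] <- NA
  out <- out[, cols]
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], signif, digits = 7)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(results)
}

#' Read association results written by [write_assoc()]
#' @param path File path.
#' @return A tibble.
#' @export
read_assoc <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
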