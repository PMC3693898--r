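# Fixtures are built in code: explicit miniature pools with known
# frequencies, plus seeded generated pools for statistical checks.

# a pool from an explicit 0/1 matrix (one block, unit positions)
pool_from_matrix <- function(mat, block = rep(1L, ncol(mat)),
                             chrom = rep("1", ncol(mat))) {
  sites <- data.frame(chrom = chrom, pos_bp = seq_len(ncol(mat)),
                      block = block, freq = colMeans(mat),
                      stringsAsFactors = FALSE)
  seqcohort:::validate_pool(seqcohort:::new_haplotype_pool(mat, sites))
}

# one biallelic site with a given derived-allele count out of n haplotypes
single_site_pool <- function(n = 1000L, n_derived = 300L) {
  m <- matrix(0L, n, 1)
  m[seq_len(n_derived), 1] <- 1L
  pool_from_matrix(m)
}

# small multi-site pool used across cohort tests (20 haplotypes, 2 blocks)
toy_pool <- function() {
  set.seed(42)
  m <- matrix(rbinom(20 * 8, 1, 0.4), 20, 8)
  # ensure polymorphic columns
  m[1, ] <- 1L
  m[2, ] <- 0L
  pool_from_matrix(m, block = rep(1:2, each = 4))
}

write_phased_vcf <- function(path, gt, chrom = "1", pos = NULL) {
  # gt: records x samples character matrix like "0|1"
  if (is.null(pos)) pos <- seq_len(nrow(gt)) * 100
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("S", seq_len(ncol(gt)))), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gt)), function(i) {
    paste(c(chrom, pos[i], paste0("v", i), "A", "T", ".", "PASS", ".",
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# HWE genotype frequencies for derived-allele count 0/1/2 at derived freq f
hwe_freqs <- function(f) c((1 - f)^2, 2 * f * (1 - f), f^2)
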