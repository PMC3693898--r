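# Haplotype pool: the finite population of phased 0/1 sequences from which
# founders and unrelated individuals are drawn under random mating.  Sites
# are grouped into recombination-free blocks; allele 1 is always the derived
# (mutant) allele.

new_haplotype_pool <- function(matrix, sites) {
  stopifnot(is.matrix(matrix), nrow(sites) == ncol(matrix))
  structure(
    list(matrix = matrix, sites = sites),
    class = "haplotype_pool"
  )
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf(
    "<haplotype_pool> %d haplotypes x %d sites in %d block(s) on %d chromosome(s)\n",
    n_haplotypes(x), n_sites(x), length(unique(x$sites$block)),
    length(unique(x$sites$chrom))
  ))
  invisible(x)
}

#' Number of haplotypes / sites in a pool
#' @param pool A `haplotype_pool`.
#' @return Integer count.
#' @export
n_haplotypes <- function(pool) nrow(pool$matrix)

#' @rdname n_haplotypes
#' @export
n_sites <- function(pool) ncol(pool$matrix)

validate_pool <- function(pool) {
  m <- pool$matrix
  s <- pool$sites
  if (!all(m %in% c(0L, 1L))) stop("pool matrix entries must be 0/1")
  if (ncol(m) > 0) {
    f <- colMeans(m)
    if (any(f <= 0 | f >= 1)) stop("pool contains monomorphic sites")
    if (any(abs(f - s$freq) > 1e-12)) stop("site frequencies out of sync")
    for (ch in unique(s$chrom)) {
      p <- s$pos_bp[s$chrom == ch]
      if (any(diff(p) <= 0)) stop("positions must strictly increase within a chromosome")
    }
    if (is.unsorted(s$block)) stop("block ids must be non-decreasing")
  }
  invisible(pool)
}

# -- built-in generator ------------------------------------------------------

# One neutral coalescent genealogy (Hudson's algorithm, constant population
# size) with infinite-sites mutations: inter-coalescence times are
# Exp(k(k-1)/2) in units of 2N generations and each branch of length L
# receives Poisson(theta * L / 2) mutations.  Every mutation is one
# polymorphic column: carriers are the leaves below the mutated branch.
sim_coalescent_block <- function(n, theta) {
  if (n < 2) stop("need at least 2 haplotypes")
  n_nodes <- 2L * n - 1L
  desc <- vector("list", n_nodes)
  desc[seq_len(n)] <- as.list(seq_len(n))
  node_time <- numeric(n_nodes)
  blen <- numeric(n_nodes)            # branch above each node (root stays 0)
  active <- seq_len(n)
  t_now <- 0
  nxt <- n + 1L
  for (k in seq(n, 2L)) {
    t_now <- t_now + stats::rexp(1L, rate = k * (k - 1) / 2)
    pair <- sample.int(k, 2L)
    c1 <- active[pair[1L]]
    c2 <- active[pair[2L]]
    blen[c1] <- t_now - node_time[c1]
    blen[c2] <- t_now - node_time[c2]
    node_time[nxt] <- t_now
    desc[[nxt]] <- c(desc[[c1]], desc[[c2]])
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  n_mut <- stats::rpois(n_nodes, theta / 2 * blen)  # root branch length is 0
  total <- sum(n_mut)
  mat <- matrix(0L, nrow = n, ncol = total)
  col <- 1L
  for (v in which(n_mut > 0L)) {
    for (j in seq_len(n_mut[v])) {
      mat[desc[[v]], col] <- 1L
      col <- col + 1L
    }
  }
  mat
}

#' Generate a haplotype pool from per-block neutral coalescents
#'
#' Each block carries an independent constant-size neutral coalescent
#' genealogy with infinite-sites mutations at rate `theta_per_block`
#' (the population-scaled mutation rate, 4Nu, per block).  Blocks are laid
#' end-to-end on one chromosome, `block_span_bp` base pairs each, and sites
#' get distinct uniform positions inside their block's span.  The expected
#' number of segregating sites per block is Watterson's
#' `theta * sum(1/(1:(n-1)))`; the site-frequency spectrum is the neutral
#' 1/i spectrum, heavily enriched for rare variants at large `n_haplotypes`.
#'
#' Blocks are mutually independent.  Linkage between blocks arises
#' downstream, during gene dropping, from the recombination map; the
#' generator itself encodes no ancestral recombination.
#'
#' @param n_haplotypes Number of haplotypes in the pool (>= 2).
#' @param n_blocks Number of recombination-free blocks (>= 1).
#' @param theta_per_block Population-scaled mutation rate per block (> 0).
#' @param block_span_bp Width of each block in base pairs (default 10 kb).
#' @param chrom Chromosome label(s), recycled over blocks; give distinct
#'   labels to place blocks on different (unlinked) chromosomes.
#' @param seed Integer master seed; block `b` draws from substream `b`.
#' @return A `haplotype_pool`.
#' @examples
#' pool <- generate_block_pool(20, 2, theta_per_block = 5, seed = 1)
#' pool
#' @export
generate_block_pool <- function(n_haplotypes, n_blocks, theta_per_block,
                                block_span_bp = 10000L, chrom = "1",
                                seed = 1L) {
  if (n_haplotypes < 2) stop("n_haplotypes must be >= 2")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  if (!is.numeric(theta_per_block) || theta_per_block <= 0) {
    stop("theta_per_block must be positive")
  }
  chrom <- rep_len(as.character(chrom), n_blocks)
  mats <- vector("list", n_blocks)
  sites <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    res <- with_substream(seed, b, {
      m <- sim_coalescent_block(n_haplotypes, theta_per_block)
      s <- ncol(m)
      if (s > block_span_bp) stop("block_span_bp too small for mutation count")
      pos <- sort(sample.int(block_span_bp, s))
      # mutations are unordered; positions are assigned in column order,
      # which is itself exchangeable
      list(m = m, pos = pos)
    })
    mats[[b]] <- res$m
    s_b <- length(res$pos)
    sites[[b]] <- data.frame(
      chrom = rep(chrom[b], s_b),
      pos_bp = res$pos + (b - 1L) * block_span_bp,
      block = rep(b, s_b),
      stringsAsFactors = FALSE
    )
  }
  mat <- do.call(cbind, c(mats, list(matrix(0L, n_haplotypes, 0))))
  site_df <- do.call(rbind, sites)
  site_df$freq <- if (ncol(mat) > 0) colMeans(mat) else numeric(0)
  pool <- new_haplotype_pool(mat, site_df)
  validate_pool(pool)
}

# -- ingestion ---------------------------------------------------------------

parse_01_lines <- function(lines, what = "haplotype file") {
  keep <- nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  if (length(lines) == 0) stop(sprintf("%s is empty", what))
  bad <- grep("[^01]", lines)
  if (length(bad)) {
    stop(sprintf("%s: non-binary characters on line %d", what, which(keep)[bad[1]]))
  }
  len <- nchar(lines)
  if (length(unique(len)) != 1) {
    off <- which(len != len[1])[1]
    stop(sprintf("%s: ragged line %d (length %d, expected %d)",
                 what, which(keep)[off], len[off], len[1]))
  }
  m <- matrix(0L, nrow = length(lines), ncol = len[1])
  for (i in seq_along(lines)) {
    m[i, ] <- utf8ToInt(lines[i]) - utf8ToInt("0")
  }
  m
}

read_vcf_phased <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (nrow(vcf@gt) == 0) stop("VCF has no genotype records")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (any(is.na(gt))) stop("VCF contains missing genotypes")
  unphased <- matrix(grepl("/", gt, fixed = TRUE), nrow(gt))
  if (any(unphased)) {
    bad <- which(unphased, arr.ind = TRUE)[1, ]
    stop(sprintf("unphased genotype at record %d sample %d", bad[1], bad[2]))
  }
  alleles <- strsplit(as.vector(gt), "|", fixed = TRUE)
  if (any(lengths(alleles) != 2)) stop("VCF genotypes must be diploid")
  al <- suppressWarnings(matrix(as.integer(unlist(alleles)), nrow = 2))
  if (any(is.na(al)) || any(al > 1)) {
    stop("VCF genotypes must be biallelic 0|1 calls")
  }
  n_rec <- nrow(gt)
  n_smp <- ncol(gt)
  # gt is records x samples; haplotypes are (sample, allele-slot) pairs
  h1 <- matrix(al[1, ], nrow = n_rec, ncol = n_smp)
  h2 <- matrix(al[2, ], nrow = n_rec, ncol = n_smp)
  hap <- matrix(0L, nrow = 2 * n_smp, ncol = n_rec)
  hap[seq(1, 2 * n_smp, by = 2), ] <- t(h1)
  hap[seq(2, 2 * n_smp, by = 2), ] <- t(h2)
  fix <- vcfR::getFIX(vcf)
  list(matrix = hap,
       chrom = as.character(fix[, "CHROM"]),
       pos = as.integer(fix[, "POS"]))
}

#' Read a haplotype pool from a file
#'
#' Three dialects are accepted: `matrix01` (one haplotype per line,
#' characters 0/1, with an optional site-metadata sidecar, TSV with header
#' `chrom pos block`), `vcf_phased` (a phased diploid VCF; each sample
#' contributes two haplotypes), and `genome_out` (output of coalescent
#' sequence simulators in which haplotype lines are exactly the lines whose
#' non-whitespace characters are all 0/1).
#'
#' Monomorphic columns are dropped (with a message giving the count): they
#' carry no information and would break minor-allele-frequency selection.
#'
#' @param haplotype_path Path to the haplotype file.
#' @param sites_path Optional site metadata sidecar (`matrix01` and
#'   `genome_out` only).
#' @param format One of `"matrix01"`, `"vcf_phased"`, `"genome_out"`.
#' @return A `haplotype_pool`.
#' @export
read_pool <- function(haplotype_path, sites_path = NULL,
                      format = c("matrix01", "vcf_phased", "genome_out")) {
  format <- match.arg(format)
  sites <- NULL
  if (format == "matrix01") {
    mat <- parse_01_lines(readLines(haplotype_path), haplotype_path)
  } else if (format == "genome_out") {
    lines <- readLines(haplotype_path)
    lines <- gsub("[[:space:]]", "", lines)
    hap_lines <- lines[nzchar(lines) & !grepl("[^01]", lines)]
    if (length(hap_lines) == 0) {
      stop(sprintf("%s: no 0/1 haplotype lines found", haplotype_path))
    }
    mat <- parse_01_lines(hap_lines, haplotype_path)
  } else {
    v <- read_vcf_phased(haplotype_path)
    mat <- v$matrix
    sites <- data.frame(chrom = v$chrom, pos_bp = v$pos, block = 1L,
                        stringsAsFactors = FALSE)
  }
  if (is.null(sites)) {
    if (!is.null(sites_path)) {
      sites <- utils::read.table(sites_path, header = TRUE,
                                 stringsAsFactors = FALSE)
      need <- c("chrom", "pos", "block")
      if (!all(need %in% names(sites))) {
        stop(sprintf("%s: expected header 'chrom pos block'", sites_path))
      }
      sites <- data.frame(chrom = as.character(sites$chrom),
                          pos_bp = as.integer(sites$pos),
                          block = as.integer(sites$block),
                          stringsAsFactors = FALSE)
      if (nrow(sites) != ncol(mat)) {
        stop(sprintf("%s: %d sites but haplotypes have %d columns",
                     sites_path, nrow(sites), ncol(mat)))
      }
    } else {
      sites <- data.frame(chrom = "1", pos_bp = seq_len(ncol(mat)),
                          block = 1L, stringsAsFactors = FALSE)
    }
  }
  freq <- colMeans(mat)
  keep <- freq > 0 & freq < 1
  if (any(!keep)) {
    message(sprintf("dropped %d monomorphic site(s)", sum(!keep)))
  }
  if (!any(keep)) stop("no polymorphic sites in pool")
  mat <- mat[, keep, drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  sites$freq <- freq[keep]
  rownames(sites) <- NULL
  validate_pool(new_haplotype_pool(mat, sites))
}

#' Write a haplotype pool in matrix01 format
#'
#' Produces `<stem>.hap` (one 0/1 haplotype per line) and `<stem>.sites`
#' (TSV, header `chrom pos block`).  `read_pool()` on the written files
#' round-trips the matrix exactly.
#'
#' @param pool A `haplotype_pool`.
#' @param stem Output path stem.
#' @return Invisibly, the two paths written.
#' @export
write_pool <- function(pool, stem) {
  hap_path <- paste0(stem, ".hap")
  sites_path <- paste0(stem, ".sites")
  writeLines(apply(pool$matrix, 1, paste, collapse = ""), hap_path)
  df <- data.frame(chrom = pool$sites$chrom, pos = pool$sites$pos_bp,
                   block = pool$sites$block)
  utils::write.table(df, sites_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(hap_path, sites_path))
}

# -- site queries ------------------------------------------------------------

#' Derived allele frequency of a site
#'
#' The column mean of the pool matrix; when the derived allele is the risk
#' allele this is the risk allele frequency used by the PAR model.
#'
#' @param pool A `haplotype_pool`.
#' @param site_index 1-based site index.
#' @return Frequency in (0, 1).
#' @export
allele_frequency <- function(pool, site_index) {
  if (any(site_index < 1 | site_index > n_sites(pool))) {
    stop("site_index out of range")
  }
  pool$sites$freq[site_index]
}

#' Minor allele frequency of each site
#' @param pool A `haplotype_pool`.
#' @return Vector of `min(freq, 1 - freq)`.
#' @export
minor_allele_frequency <- function(pool) {
  pmin(pool$sites$freq, 1 - pool$sites$freq)
}

#' Select causal sites by minor allele frequency
#'
#' Draws `n` distinct site indices uniformly without replacement from the
#' sites whose minor allele frequency lies in `maf_range`, optionally
#' restricted to a set of blocks.  Deterministic given `seed`.
#'
#' @param pool A `haplotype_pool`.
#' @param n Number of sites to select.
#' @param maf_range Two-element `c(low, high)` MAF bounds (inclusive).
#' @param blocks Optional block ids to restrict to (default: all).
#' @param seed Integer seed.
#' @return Sorted integer vector of site indices.
#' @export
select_causal_sites <- function(pool, n, maf_range = c(0, 0.01),
                                blocks = NULL, seed = 1L) {
  if (n == 0) return(integer(0))
  maf <- minor_allele_frequency(pool)
  ok <- maf >= maf_range[1] & maf <= maf_range[2]
  if (!is.null(blocks)) ok <- ok & pool$sites$block %in% blocks
  idx <- which(ok)
  if (length(idx) < n) {
    stop(sprintf("only %d site(s) satisfy the MAF range; %d requested",
                 length(idx), n))
  }
  with_substream(seed, 7L, sort(idx[sample.int(length(idx), n)]))
}

#' Subset a pool to a set of sites
#'
#' Used to trim a block to a fixed-width test region.  Site order is
#' preserved; frequencies are untouched.
#'
#' @param pool A `haplotype_pool`.
#' @param sites Integer site indices (strictly increasing).
#' @return A `haplotype_pool` over the selected columns.
#' @export
subset_sites <- function(pool, sites) {
  if (any(sites < 1 | sites > n_sites(pool))) stop("site index out of range")
  if (is.unsorted(sites, strictly = TRUE)) stop("sites must be strictly increasing")
  s <- pool$sites[sites, , drop = FALSE]
  rownames(s) <- NULL
  validate_pool(new_haplotype_pool(pool$matrix[, sites, drop = FALSE], s))
}

#' Chromosome label of each block
#' @param pool A `haplotype_pool`.
#' @return Character vector indexed by block id.
#' @keywords internal
block_chroms <- function(pool) {
  nb <- max(pool$sites$block)
  out <- character(nb)
  out[pool$sites$block] <- pool$sites$chrom
  out
}

#' Block centers of a pool
#'
#' One row per block: chromosome and the midpoint (mean bp) of the block's
#' sites.  This is the per-block anchor used to build recombination maps.
#'
#' @param pool A `haplotype_pool`.
#' @return `data.frame(block, chrom, center_bp)`.
#' @export
pool_block_centers <- function(pool) {
  blocks <- unique(pool$sites$block)
  data.frame(
    block = blocks,
    chrom = vapply(blocks, function(b) {
      pool$sites$chrom[pool$sites$block == b][1]
    }, character(1)),
    center_bp = vapply(blocks, function(b) {
      mean(pool$sites$pos_bp[pool$sites$block == b])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}
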