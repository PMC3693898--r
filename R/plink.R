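# PLINK text output: original ped (6 leading columns + 2 alleles per site)
# and 4-column map (chrom, snp id, genetic position in cM, bp), plus the
# sidecar quantitative phenotype file (FID IID PHENO, no header).
#
# Alleles are coded 1 = ancestral, 2 = derived.  Genetic positions
# accumulate Haldane-converted interval distances from the first block of
# each chromosome; sites within a block share one position.

ped_pheno_column <- function(members) {
  if (any(members$aff != 0L)) {
    members$aff                      # 1 = unaffected, 2 = affected, 0 = unknown
  } else if (!all(is.na(members$trait))) {
    format(members$trait, trim = TRUE, digits = 10)
  } else {
    rep(0L, nrow(members))
  }
}

#' Write a cohort as a PLINK ped file
#'
#' One row per individual: `FID IID PAT MAT SEX PHENO` followed by two
#' allele columns per site (1 = ancestral, 2 = derived).  The phenotype
#' column holds affection status (1/2, 0 = unknown) when a disease was
#' simulated, otherwise the quantitative trait.
#'
#' @param cohort A `cohort`.
#' @param pool The `haplotype_pool` it was simulated from.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(cohort, pool, path) {
  m <- cohort$members
  if (all(m$aff == 0L) && all(is.na(m$trait))) {
    stop("cohort has no phenotypes; simulate a disease or trait first")
  }
  sites <- seq_len(n_sites(pool))
  a1 <- geno_from_haps(pool, cohort$hap1, cohort$hap1, sites) / 2L + 1L
  a2 <- geno_from_haps(pool, cohort$hap2, cohort$hap2, sites) / 2L + 1L
  geno <- matrix(0L, nrow(a1), 2L * ncol(a1))
  geno[, seq(1, 2 * ncol(a1), by = 2)] <- a1
  geno[, seq(2, 2 * ncol(a1), by = 2)] <- a2
  lead <- paste(m$fid, m$iid, m$pat, m$mat, m$sex, ped_pheno_column(m))
  writeLines(paste(lead, apply(geno, 1, paste, collapse = " ")), path)
  invisible(path)
}

#' SNP identifiers used in map files
#' @param pool A `haplotype_pool`.
#' @param rmap The matching `recomb_map`.
#' @return Character vector `chr<k>_b<block>_<bp>`, one per site.
#' @keywords internal
snp_ids <- function(pool, rmap) {
  chrom_of_block <- map_chromosomes(rmap)
  sprintf("chr%d_b%d_%d", chrom_of_block[pool$sites$block],
          pool$sites$block, pool$sites$pos_bp)
}

#' Write the PLINK map file
#'
#' Four columns: chromosome number, SNP id, genetic position (cM) and bp
#' position.  Chromosome numbers follow the map's chromosome breaks
#' (theta = 0.5 intervals).  Within a block all sites share the block's
#' cumulative cM position; block-to-block increments are
#' `haldane_theta_to_cm(theta_i)`.
#'
#' @param pool A `haplotype_pool`.
#' @param rmap The matching `recomb_map`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_map <- function(pool, rmap, path) {
  if (length(rmap$centers_bp) < max(pool$sites$block)) {
    stop("recombination map has fewer blocks than the pool")
  }
  chrom_of_block <- map_chromosomes(rmap)
  cm_of_block <- map_positions_cm(rmap)
  b <- pool$sites$block
  df <- data.frame(
    chrom = chrom_of_block[b],
    id = snp_ids(pool, rmap),
    cm = cm_of_block[b],
    bp = pool$sites$pos_bp
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the quantitative phenotype file
#'
#' `FID IID PHENO`, whitespace-delimited, no header — the PLINK alternate
#' phenotype format.
#'
#' @param cohort A phenotyped `cohort` with trait values.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pheno <- function(cohort, path) {
  m <- cohort$members
  if (all(is.na(m$trait))) stop("cohort has no trait values")
  writeLines(paste(m$fid, m$iid, format(m$trait, trim = TRUE, digits = 10)),
             path)
  invisible(path)
}

#' Read a PLINK text ped file
#'
#' Parses the documented `6 + 2S` whitespace grammar back into the leading
#' pedigree columns and an allele matrix; the inverse of [write_ped()] up
#' to allele coding.
#'
#' @param path Path to a ped file.
#' @return List with `info` (data.frame of the 6 leading columns) and
#'   `alleles` (integer matrix, individuals x 2S).
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  len <- lengths(fields)
  if (any(len < 8) || length(unique(len)) != 1) {
    stop("malformed ped file: ragged or short rows")
  }
  info <- data.frame(
    fid = vapply(fields, `[[`, character(1), 1),
    iid = vapply(fields, `[[`, character(1), 2),
    pat = vapply(fields, `[[`, character(1), 3),
    mat = vapply(fields, `[[`, character(1), 4),
    sex = as.integer(vapply(fields, `[[`, character(1), 5)),
    pheno = vapply(fields, `[[`, character(1), 6),
    stringsAsFactors = FALSE
  )
  alleles <- t(vapply(fields, function(f) as.integer(f[-(1:6)]),
                      integer(len[1] - 6L)))
  list(info = info, alleles = alleles)
}

#' Write a cohort as a full PLINK file set
#'
#' Convenience wrapper producing `<prefix>.ped`, `<prefix>.map` and, when
#' trait values are present, `<prefix>.phe`.
#'
#' @param cohort A `cohort`.
#' @param pool,rmap The pool and map the cohort was simulated from.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_plink <- function(cohort, pool, rmap, prefix) {
  paths <- c(write_ped(cohort, pool, paste0(prefix, ".ped")),
             write_map(pool, rmap, paste0(prefix, ".map")))
  if (!all(is.na(cohort$members$trait))) {
    paths <- c(paths, write_pheno(cohort, paste0(prefix, ".phe")))
  }
  invisible(paths)
}
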