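# Cohort simulation: gene-dropping in three-generation pedigrees with
# affected-sibling ascertainment, and unrelated case-control sampling with
# an optional fast conditional-genotype case sampler.
#
# A haplotype is represented as a block mosaic: an integer vector giving,
# for every block, the pool haplotype whose block it copies.  Since there
# is no recombination within blocks, this representation is lossless, and
# meiosis is a Markov switch process over the block sequence.

new_cohort <- function(members, hap1, hap2, design) {
  structure(
    list(members = members, hap1 = hap1, hap2 = hap2, design = design),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d individual(s) in %d famil(y/ies), design = %s\n",
              nrow(x$members), length(unique(x$members$fid)), x$design))
  invisible(x)
}

# derived-allele counts of cohort members at the given sites
#' Genotypes of cohort members
#'
#' Derived-allele counts (0/1/2) at the requested sites, reconstructed
#' from the block-mosaic haplotypes against the pool.
#'
#' @param cohort A `cohort`.
#' @param pool The `haplotype_pool` the cohort was simulated from.
#' @param sites Site indices (default: all).
#' @return Integer matrix, individuals x sites.
#' @export
cohort_genotypes <- function(cohort, pool, sites = seq_len(n_sites(pool))) {
  geno_from_haps(pool, cohort$hap1, cohort$hap2, sites)
}

geno_from_haps <- function(pool, hapA, hapB, sites) {
  n <- nrow(hapA)
  G <- matrix(0L, n, length(sites))
  blk <- pool$sites$block[sites]
  for (b in unique(blk)) {
    j <- which(blk == b)
    cols <- sites[j]
    G[, j] <- pool$matrix[hapA[, b], cols, drop = FALSE] +
      pool$matrix[hapB[, b], cols, drop = FALSE]
  }
  G
}

# one founder haplotype pair as block-mosaic rows (uses the current stream);
# each chromosome draws its own independent pool row, enforcing linkage
# equilibrium across (unlinked) chromosomes while keeping the pool's full
# haplotype structure within a chromosome
draw_founder_rows <- function(pool, chrom_of_block) {
  N <- n_haplotypes(pool)
  uc <- unique(chrom_of_block)
  r1 <- sample.int(N, length(uc), replace = TRUE)
  r2 <- sample.int(N, length(uc), replace = TRUE)
  idx <- match(chrom_of_block, uc)
  list(h1 = r1[idx], h2 = r2[idx])
}

#' Draw a founder haplotype pair
#'
#' Two haplotypes drawn uniformly with replacement from the pool (random
#' mating), expressed as block mosaics.  On a single-chromosome pool each
#' haplotype is one intact pool row; pools spanning several chromosomes
#' draw an independent row per chromosome (chromosomes segregate
#' independently, so the population is in linkage equilibrium across
#' them).
#'
#' @param pool A `haplotype_pool`.
#' @param seed Integer seed.
#' @return List with integer vectors `h1`, `h2` (pool row per block).
#' @export
draw_founder <- function(pool, seed = 1L) {
  if (n_haplotypes(pool) < 1) stop("empty pool")
  with_substream(seed, 31L, draw_founder_rows(pool, block_chroms(pool)))
}

# gamete from a parental pair; uses the current stream
meiosis_rows <- function(h1, h2, theta) {
  nb <- length(h1)
  start <- sample.int(2L, 1L)
  switches <- if (nb > 1) stats::runif(nb - 1L) < theta else logical(0)
  state <- (start - 1L + cumsum(c(0L, as.integer(switches)))) %% 2L
  ifelse(state == 0L, h1, h2)
}

#' Simulate one meiosis
#'
#' The gamete starts from a fair-coin choice of parental haplotype for the
#' first block and switches haplotypes between adjacent blocks `i` and
#' `i+1` with probability `theta_i`, independently across intervals (no
#' interference).  Blocks are transmitted intact.
#'
#' @param parent List with block-mosaic haplotypes `h1`, `h2`.
#' @param rmap A `recomb_map` whose intervals match the haplotype length.
#' @param seed Integer seed.
#' @return Integer block-mosaic gamete.
#' @export
meiosis <- function(parent, rmap, seed = 1L) {
  if (length(parent$h1) != length(rmap$centers_bp)) {
    stop("recombination map does not match the haplotypes' block count")
  }
  with_substream(seed, 37L, meiosis_rows(parent$h1, parent$h2, rmap$theta))
}

# -- pedigrees ---------------------------------------------------------------

#' Simulate one three-generation pedigree
#'
#' Generation 1: two founder couples (4 founders drawn from the pool).
#' Generation 2: the father (child of couple A) and the mother (child of
#' couple B), each produced by meiosis; no married-in spouses.
#' Generation 3: `n_sibs` full siblings of the generation-2 couple.  With
#' the default of 6 siblings the family has 12 members.
#'
#' Affection status (if a disease spec is given) is assigned to every
#' member by comparing the penetrance of their causal genotype to a
#' uniform variate; traits (if a QTL spec is given) are sampled for every
#' member.
#'
#' @param pool A `haplotype_pool`.
#' @param rmap A `recomb_map` over the pool's blocks.
#' @param disease Optional `disease_spec` (resolved).
#' @param trait Optional `qtl_spec`.
#' @param n_sibs Number of third-generation siblings (default 6).
#' @param fid Family id string.
#' @param seed Integer seed.
#' @return A single-family `cohort`; `members` carries a `gen` column.
#' @export
simulate_family <- function(pool, rmap, disease = NULL, trait = NULL,
                            n_sibs = 6L, fid = "fam1", seed = 1L) {
  if (is.null(disease) && is.null(trait)) {
    stop("supply a disease spec, a trait spec, or both")
  }
  nb <- length(rmap$centers_bp)
  if (nb != max(pool$sites$block)) {
    stop("recombination map does not cover the pool's blocks")
  }
  cb <- block_chroms(pool)
  n_mem <- 6L + n_sibs
  with_substream(seed, 41L, {
    h1 <- matrix(0L, n_mem, nb)
    h2 <- matrix(0L, n_mem, nb)
    for (i in 1:4) {
      f <- draw_founder_rows(pool, cb)
      h1[i, ] <- f$h1
      h2[i, ] <- f$h2
    }
    # father (id 5) from couple (1, 2); mother (id 6) from couple (3, 4)
    h1[5, ] <- meiosis_rows(h1[1, ], h2[1, ], rmap$theta)
    h2[5, ] <- meiosis_rows(h1[2, ], h2[2, ], rmap$theta)
    h1[6, ] <- meiosis_rows(h1[3, ], h2[3, ], rmap$theta)
    h2[6, ] <- meiosis_rows(h1[4, ], h2[4, ], rmap$theta)
    for (k in seq_len(n_sibs)) {
      i <- 6L + k
      h1[i, ] <- meiosis_rows(h1[5, ], h2[5, ], rmap$theta)
      h2[i, ] <- meiosis_rows(h1[6, ], h2[6, ], rmap$theta)
    }
    members <- data.frame(
      fid = fid,
      iid = seq_len(n_mem),
      pat = c(0L, 0L, 0L, 0L, 1L, 3L, rep(5L, n_sibs)),
      mat = c(0L, 0L, 0L, 0L, 2L, 4L, rep(6L, n_sibs)),
      sex = c(1L, 2L, 1L, 2L, 1L, 2L, rep_len(c(1L, 2L), n_sibs)),
      gen = c(1L, 1L, 1L, 1L, 2L, 2L, rep(3L, n_sibs)),
      aff = 0L,
      trait = NA_real_,
      stringsAsFactors = FALSE
    )
    if (!is.null(disease)) {
      counts <- geno_from_haps(pool, h1, h2, disease$causal_sites)
      pen <- penetrance(disease, counts)
      members$aff <- ifelse(stats::runif(n_mem) < pen, 2L, 1L)
    }
    if (!is.null(trait)) {
      counts <- geno_from_haps(pool, h1, h2, trait$qtl_sites)
      ts <- sample.int(2147483646L, 1L)
      members$trait <- sample_trait(trait, counts, seed = ts)
    }
    new_cohort(members, h1, h2, design = "family")
  })
}

#' Affected-sibling ascertainment rule
#'
#' A family is ascertained if at least `s` third-generation siblings are
#' affected.  Generations 1-2 also carry affection status but never enter
#' the rule.
#'
#' @param ped A single-family `cohort` from [simulate_family()].
#' @param s Required number of affected siblings (typically 1-3).
#' @return `TRUE` or `FALSE`.
#' @export
ascertain <- function(ped, s) {
  sum(ped$members$aff == 2L & ped$members$gen == 3L) >= s
}

bind_cohorts <- function(cohorts, design) {
  new_cohort(
    do.call(rbind, lapply(cohorts, `[[`, "members")),
    do.call(rbind, lapply(cohorts, `[[`, "hap1")),
    do.call(rbind, lapply(cohorts, `[[`, "hap2")),
    design = design
  )
}

#' Simulate an ascertained family sample
#'
#' Rejection-samples pedigrees until `n_families` pass the
#' affected-sibling rule (or, with `ascertain_mode = "random"`, keeps every
#' family).  Each family slot draws from its own keyed substream of the
#' master seed, so the output is identical for any number of workers; the
#' `n_workers` argument only partitions the slots.
#'
#' @param pool,rmap,disease,trait,n_sibs As in [simulate_family()].
#' @param n_families Number of families to return.
#' @param s Required affected third-generation siblings.
#' @param ascertain_mode `"affected"` (default when a disease spec is
#'   present) or `"random"` (no rejection; the only choice for pure
#'   trait simulations).
#' @param seed Master seed.
#' @param n_workers Worker count (partitioning only; results are
#'   worker-invariant).
#' @return A `cohort` of `n_families` pedigrees, with attribute
#'   `acceptance_rate`.
#' @export
simulate_families <- function(pool, rmap, disease = NULL, trait = NULL,
                              n_families, s = 1L,
                              ascertain_mode = if (is.null(disease)) "random" else "affected",
                              n_sibs = 6L, seed = 1L, n_workers = 1L) {
  ascertain_mode <- match.arg(ascertain_mode, c("affected", "random"))
  if (ascertain_mode == "affected" && is.null(disease)) {
    stop("affected-sibling ascertainment requires a disease spec")
  }
  if (ascertain_mode == "affected" && s > n_sibs) {
    stop("required affected siblings exceeds sibship size")
  }
  slots <- split(seq_len(n_families),
                 rep_len(seq_len(max(n_workers, 1L)), n_families))
  fams <- vector("list", n_families)
  attempts_total <- 0L
  for (w in seq_along(slots)) {
    for (i in slots[[w]]) {
      slot_seed <- substream_seed(seed, 100000L + i)
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        if (attempt > 1000L) {
          stop(sprintf(
            "ascertainment failed: 1000 consecutive rejections for family %d (acceptance rate ~%.2g)",
            i, (i - 1) / max(attempts_total, 1)))
        }
        ped <- simulate_family(pool, rmap, disease, trait, n_sibs,
                               fid = sprintf("fam%d", i),
                               seed = substream_seed(slot_seed, attempt))
        attempts_total <- attempts_total + 1L
        if (ascertain_mode == "random" || ascertain(ped, s)) break
      }
      fams[[i]] <- ped
    }
  }
  out <- bind_cohorts(fams, design = "family")
  attr(out, "acceptance_rate") <- n_families / attempts_total
  out
}

# -- unrelated case-control --------------------------------------------------

# one third-generation child of an otherwise discarded pedigree
thirdgen_rows <- function(pool, theta, cb) {
  gp <- replicate(4, draw_founder_rows(pool, cb), simplify = FALSE)
  fa <- list(h1 = meiosis_rows(gp[[1]]$h1, gp[[1]]$h2, theta),
             h2 = meiosis_rows(gp[[2]]$h1, gp[[2]]$h2, theta))
  mo <- list(h1 = meiosis_rows(gp[[3]]$h1, gp[[3]]$h2, theta),
             h2 = meiosis_rows(gp[[4]]$h1, gp[[4]]$h2, theta))
  list(h1 = meiosis_rows(fa$h1, fa$h2, theta),
       h2 = meiosis_rows(mo$h1, mo$h2, theta))
}

# rejection sampling of unrelated individuals conditional on affection;
# vectorized over batches.  Under random mating a third-generation child's
# marginal block-level genotype distribution equals the founder
# distribution, so by default individuals are drawn directly as founder
# pairs; faithful_thirdgen = TRUE runs the literal gene-dropping procedure.
draw_unrelated_by_status <- function(pool, disease, n, affected, rmap = NULL,
                                     faithful_thirdgen = FALSE) {
  nb <- max(pool$sites$block)
  cb <- block_chroms(pool)
  if (faithful_thirdgen && is.null(rmap)) {
    stop("faithful_thirdgen requires a recombination map")
  }
  theta <- if (is.null(rmap)) numeric(0) else rmap$theta
  N <- n_haplotypes(pool)
  got <- 0L
  H1 <- matrix(0L, n, nb)
  H2 <- matrix(0L, n, nb)
  attempts <- 0L
  while (got < n) {
    batch <- max(1000L, 4L * (n - got))
    if (faithful_thirdgen) {
      b1 <- matrix(0L, batch, nb)
      b2 <- matrix(0L, batch, nb)
      for (i in seq_len(batch)) {
        tg <- thirdgen_rows(pool, theta, cb)
        b1[i, ] <- tg$h1
        b2[i, ] <- tg$h2
      }
    } else {
      b1 <- matrix(0L, batch, nb)
      b2 <- matrix(0L, batch, nb)
      for (ch in unique(cb)) {
        b1[, cb == ch] <- sample.int(N, batch, replace = TRUE)
        b2[, cb == ch] <- sample.int(N, batch, replace = TRUE)
      }
    }
    counts <- geno_from_haps(pool, b1, b2, disease$causal_sites)
    pen <- penetrance(disease, counts)
    keep <- if (affected) stats::runif(batch) < pen else stats::runif(batch) >= pen
    attempts <- attempts + batch
    idx <- which(keep)
    if (length(idx) > 0) {
      take <- idx[seq_len(min(length(idx), n - got))]
      H1[got + seq_along(take), ] <- b1[take, , drop = FALSE]
      H2[got + seq_along(take), ] <- b2[take, , drop = FALSE]
      got <- got + length(take)
    }
    if (attempts > 1000 * n && got == 0L) {
      stop(sprintf("rejection sampling stalled: 0/%d accepted", attempts))
    }
  }
  list(h1 = H1, h2 = H2)
}

#' Simulate unrelated affected individuals by rejection
#'
#' Repeatedly draws random-mating individuals and keeps those whose
#' penetrance draw marks them affected (cases) or unaffected (controls).
#'
#' @param pool A `haplotype_pool`.
#' @param disease A resolved `disease_spec`.
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param rmap Optional `recomb_map` (needed only with
#'   `faithful_thirdgen`).
#' @param faithful_thirdgen Draw each individual literally as the
#'   third-generation child of a discarded pedigree instead of as a
#'   founder pair (the two are distributionally identical under random
#'   mating).
#' @return List of block-mosaic haplotype matrices `h1`, `h2`.
#' @export
simulate_cases_rejection <- function(pool, disease, n, seed = 1L,
                                     rmap = NULL, faithful_thirdgen = FALSE) {
  with_substream(seed, 43L,
    draw_unrelated_by_status(pool, disease, n, TRUE, rmap, faithful_thirdgen))
}

#' @rdname simulate_cases_rejection
#' @export
simulate_controls <- function(pool, disease, n, seed = 1L,
                              rmap = NULL, faithful_thirdgen = FALSE) {
  with_substream(seed, 47L,
    draw_unrelated_by_status(pool, disease, n, FALSE, rmap, faithful_thirdgen))
}

# -- fast conditional case sampler -------------------------------------------

#' Fit the case-conditional genotype distribution
#'
#' The empirical frequency table of multilocus causal genotype vectors
#' observed in a pilot set of rejection-sampled cases; this estimates
#' P(X | affected) and drives [sample_case_fast()], whose runtime is then
#' independent of the disease prevalence.  The estimate carries the
#' pilot's sampling error, so small pilots reproduce the rejection
#' sampler's genotype distribution only approximately.
#'
#' @param pilot_counts Matrix of derived-allele counts at the causal sites
#'   for the pilot cases (one row per case).
#' @return A `case_conditional`: unique genotype vectors with
#'   probabilities summing to one.
#' @export
fit_case_conditional <- function(pilot_counts) {
  if (!is.matrix(pilot_counts)) pilot_counts <- matrix(pilot_counts, nrow = 1)
  if (nrow(pilot_counts) < 1) stop("need at least one pilot case")
  key <- apply(pilot_counts, 1, paste, collapse = "")
  tab <- table(key)
  levels <- pilot_counts[match(names(tab), key), , drop = FALSE]
  structure(
    list(levels = levels, prob = as.numeric(tab) / sum(tab)),
    class = "case_conditional"
  )
}

# all ways to split a multilocus genotype into two haplotype allele vectors:
# het loci are assigned to haplotype A or B; enumeration is capped and the
# sampler falls back to random phase draws beyond the cap
phase_options <- function(x, hap_keys_env, max_enum = 12L) {
  het <- which(x == 1L)
  base <- as.integer(x == 2L)
  if (length(het) > max_enum) return(NULL)
  n_opt <- 2^length(het)
  opts <- vector("list", n_opt)
  kept <- 0L
  for (m in seq_len(n_opt) - 1L) {
    a <- base
    bits <- as.integer(intToBits(m)[seq_along(het)])
    a[het] <- bits
    b <- x - a
    ka <- paste(a, collapse = "")
    kb <- paste(b, collapse = "")
    rows_a <- hap_keys_env[[ka]]
    rows_b <- hap_keys_env[[kb]]
    if (!is.null(rows_a) && !is.null(rows_b)) {
      kept <- kept + 1L
      opts[[kept]] <- list(rows_a = rows_a, rows_b = rows_b)
    }
  }
  if (kept == 0L) return(list())
  opts[seq_len(kept)]
}

#' Fast case sampling from the conditional genotype distribution
#'
#' Draws a multilocus causal genotype X from the fitted conditional
#' distribution, picks a phase assignment uniformly among the assignments
#' consistent with at least one pool haplotype pair, then draws each
#' haplotype uniformly from the pool haplotypes matching its causal-site
#' allele vector.  The sampled individual is labeled affected without any
#' penetrance evaluation.  Chromosomes not carrying causal sites are
#' filled with ordinary founder draws (they are independent of affection
#' given the causal genotype); all causal sites must lie on one
#' chromosome.
#'
#' @param cond A `case_conditional` from [fit_case_conditional()].
#' @param pool A `haplotype_pool`.
#' @param causal_sites Causal site indices (same order as the fit).
#' @param n Number of cases.
#' @param seed Integer seed.
#' @param n_blocks Number of blocks for the mosaic representation.
#' @return List of block-mosaic haplotype matrices `h1`, `h2`.
#' @export
sample_case_fast <- function(cond, pool, causal_sites, n, seed = 1L,
                             n_blocks = max(pool$sites$block)) {
  cb <- block_chroms(pool)
  causal_chrom <- unique(cb[pool$sites$block[causal_sites]])
  if (length(causal_chrom) > 1) {
    stop("fast case sampler requires all causal sites on one chromosome; ",
         "use the rejection sampler for multi-chromosome disease loci")
  }
  cc_cols <- which(cb == causal_chrom)
  other_chroms <- setdiff(unique(cb), causal_chrom)
  cs_mat <- pool$matrix[, causal_sites, drop = FALSE]
  keys <- apply(cs_mat, 1, paste, collapse = "")
  env <- new.env(parent = emptyenv(), size = length(unique(keys)))
  for (g in split(seq_along(keys), keys)) {
    assign(keys[g[1]], g, envir = env)
  }
  n_lev <- nrow(cond$levels)
  opts <- lapply(seq_len(n_lev), function(i) {
    phase_options(cond$levels[i, ], env)
  })
  feasible <- vapply(opts, function(o) is.null(o) || length(o) > 0, logical(1))
  if (!any(feasible & cond$prob > 0)) {
    stop("no conditional genotype is consistent with any pool haplotype pair")
  }
  with_substream(seed, 53L, {
    H1 <- matrix(0L, n, n_blocks)
    H2 <- matrix(0L, n, n_blocks)
    for (i in seq_len(n)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > 1000L) {
          stop("fast case sampler: no consistent haplotype pair after 1000 genotype redraws")
        }
        lev <- sample.int(n_lev, 1L, prob = cond$prob)
        o <- opts[[lev]]
        if (is.null(o)) {            # too many hets to enumerate: random phase
          o <- list()
          x <- cond$levels[lev, ]
          het <- which(x == 1L)
          base <- as.integer(x == 2L)
          for (try in 1:100) {
            a <- base
            a[het] <- as.integer(stats::runif(length(het)) < 0.5)
            ra <- env[[paste(a, collapse = "")]]
            rb <- env[[paste(x - a, collapse = "")]]
            if (!is.null(ra) && !is.null(rb)) {
              o <- list(list(rows_a = ra, rows_b = rb))
              break
            }
          }
        }
        if (length(o) > 0) {
          ph <- o[[sample.int(length(o), 1L)]]
          r1 <- ph$rows_a[sample.int(length(ph$rows_a), 1L)]
          r2 <- ph$rows_b[sample.int(length(ph$rows_b), 1L)]
          H1[i, cc_cols] <- r1
          H2[i, cc_cols] <- r2
          break
        }
      }
    }
    # unlinked chromosomes are independent of affection status given the
    # causal genotype: fill them with ordinary founder draws
    N <- n_haplotypes(pool)
    for (ch in other_chroms) {
      H1[, cb == ch] <- sample.int(N, n, replace = TRUE)
      H2[, cb == ch] <- sample.int(N, n, replace = TRUE)
    }
    list(h1 = H1, h2 = H2)
  })
}

#' Simulate an unrelated case-control sample
#'
#' Cases and controls are unrelated random-mating individuals conditioned
#' on affection status.  With `fast_mode` the cases come from the
#' conditional-genotype sampler seeded by a pilot of `pilot_cases`
#' rejection-sampled cases, so case generation does not slow down as the
#' prevalence falls; controls always use rejection (they are cheap unless
#' the disease is nearly universal).
#'
#' @param pool A `haplotype_pool`.
#' @param disease A resolved `disease_spec`.
#' @param n_cases,n_controls Sample sizes.
#' @param fast_mode Use the conditional case sampler.
#' @param pilot_cases Pilot size for [fit_case_conditional()] (default
#'   100).
#' @param trait Optional `qtl_spec`: traits are sampled for every
#'   individual.
#' @param seed Master seed.
#' @param rmap,faithful_thirdgen Passed to the rejection samplers.
#' @return A `cohort`; each individual is its own single-member family
#'   (`case<i>` / `ctrl<i>`), cases have `aff = 2`, controls `aff = 1`.
#' @export
simulate_case_control <- function(pool, disease, n_cases, n_controls,
                                  fast_mode = FALSE, pilot_cases = 100L,
                                  trait = NULL, seed = 1L,
                                  rmap = NULL, faithful_thirdgen = FALSE) {
  nb <- max(pool$sites$block)
  if (fast_mode) {
    pilot <- simulate_cases_rejection(pool, disease, pilot_cases, seed = seed,
                                      rmap = rmap,
                                      faithful_thirdgen = faithful_thirdgen)
    pcounts <- geno_from_haps(pool, pilot$h1, pilot$h2, disease$causal_sites)
    cond <- fit_case_conditional(pcounts)
    cases <- sample_case_fast(cond, pool, disease$causal_sites, n_cases,
                              seed = seed, n_blocks = nb)
  } else {
    cases <- simulate_cases_rejection(pool, disease, n_cases, seed = seed,
                                      rmap = rmap,
                                      faithful_thirdgen = faithful_thirdgen)
  }
  ctrls <- simulate_controls(pool, disease, n_controls, seed = seed,
                             rmap = rmap,
                             faithful_thirdgen = faithful_thirdgen)
  members <- data.frame(
    fid = c(sprintf("case%d", seq_len(n_cases)),
            sprintf("ctrl%d", seq_len(n_controls))),
    iid = 1L,
    pat = 0L, mat = 0L,
    sex = rep_len(c(1L, 2L), n_cases + n_controls),
    gen = 1L,
    aff = rep(c(2L, 1L), c(n_cases, n_controls)),
    trait = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- new_cohort(members,
                    rbind(cases$h1, ctrls$h1),
                    rbind(cases$h2, ctrls$h2),
                    design = "cc")
  if (!is.null(trait)) {
    counts <- cohort_genotypes(out, pool, trait$qtl_sites)
    out$members$trait <- sample_trait(trait, counts,
                                      seed = substream_seed(seed, 59L))
  }
  out
}

#' Mendelian consistency audit
#'
#' Checks that every non-founder's paternal (maternal) haplotype copies,
#' block by block, one of the father's (mother's) two haplotypes.  With the
#' block-mosaic representation this is exactly the statement that each
#' gamete decomposes into parental segments with breakpoints at block
#' boundaries.
#'
#' @param cohort A `cohort`.
#' @return `TRUE` if consistent; otherwise a data.frame of violations.
#' @export
audit_mendelian <- function(cohort) {
  m <- cohort$members
  bad <- NULL
  for (i in which(m$pat > 0L)) {
    fa <- which(m$fid == m$fid[i] & m$iid == m$pat[i])
    mo <- which(m$fid == m$fid[i] & m$iid == m$mat[i])
    ok_p <- cohort$hap1[i, ] == cohort$hap1[fa, ] |
      cohort$hap1[i, ] == cohort$hap2[fa, ]
    ok_m <- cohort$hap2[i, ] == cohort$hap1[mo, ] |
      cohort$hap2[i, ] == cohort$hap2[mo, ]
    if (!all(ok_p) || !all(ok_m)) {
      bad <- rbind(bad, data.frame(fid = m$fid[i], iid = m$iid[i],
                                   block = which(!(ok_p & ok_m))))
    }
  }
  if (is.null(bad)) TRUE else bad
}
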