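# Quantitative trait model: Y = mu + sum_j G_j + P + E, where G_j is the
# genotypic value at QTL j, P ~ N(0, V_poly) is the polygenic component and
# E ~ N(0, V_P - sum_j V_Pj - V_poly) the environmental residual.
#
# Each QTL explains a fraction f_j of the total phenotypic variance V_P
# (V_Pj = V_P * f_j).  The genotypic value a_j is chosen so that the
# variance of the three-point genotype means over Hardy-Weinberg genotype
# frequencies is exactly V_Pj; A1 denotes the minor allele and carries the
# larger trait value.

#' Genotypic value of a QTL from its explained variance
#'
#' With minor allele frequency `p` (and `q = 1 - p`), the genotypic value
#' is `a = sqrt(V_Pj / D)` where the denominator `D` is `2pq` (additive),
#' `8pq^3 + 4p^2q^2` (dominant) or `8p^3q + 4p^2q^2` (recessive).  `D` is
#' precisely the variance of the three genotype means (below) taken over
#' Hardy-Weinberg genotype frequencies, divided by `a^2`, so the QTL
#' explains exactly `V_Pj = V_P * f_j` of the phenotypic variance.
#'
#' @param V_P Total phenotypic variance (> 0).
#' @param f_j Fraction of variance explained by this QTL, in `[0, 1)`.
#' @param p Minor allele (A1) frequency in (0, 1).
#' @param mode Inheritance mode.
#' @return The genotypic value `a_j >= 0`.
#' @export
genotypic_value <- function(V_P, f_j, p,
                            mode = c("additive", "dominant", "recessive")) {
  mode <- match.arg(mode)
  if (V_P <= 0) stop("V_P must be positive")
  if (f_j < 0 || f_j >= 1) stop("f_j must lie in [0, 1)")
  if (p <= 0 || p >= 1) stop("allele frequency must lie in (0, 1)")
  q <- 1 - p
  denom <- switch(mode,
    additive  = 2 * p * q,
    dominant  = 8 * p * q^3 + 4 * p^2 * q^2,
    recessive = 8 * p^3 * q + 4 * p^2 * q^2
  )
  sqrt(V_P * f_j / denom)
}

#' Genotype mean of a QTL
#'
#' For genotypes A1A1 / A1A2 / A2A2 (A1 the minor, trait-increasing
#' allele) the means are `(a, 0, -a)` under the additive model,
#' `(a, a, -a)` under the dominant model and `(a, -a, -a)` under the
#' recessive model.
#'
#' @param a1_count Number of A1 alleles, in `{0, 1, 2}` (vectorized).
#' @param a_j Genotypic value from [genotypic_value()].
#' @param mode Inheritance mode.
#' @return Genotype mean(s) `mu_j`.
#' @export
locus_mean <- function(a1_count, a_j,
                       mode = c("additive", "dominant", "recessive")) {
  mode <- match.arg(mode)
  if (any(!a1_count %in% c(0L, 1L, 2L))) stop("allele counts must be 0, 1 or 2")
  by_count <- switch(mode,              # index = a1_count + 1
    additive  = c(-1, 0, 1),
    dominant  = c(-1, 1, 1),
    recessive = c(-1, -1, 1)
  )
  out <- a_j * by_count[a1_count + 1L]
  if (is.matrix(a1_count)) dim(out) <- dim(a1_count)
  out
}

#' Specify a quantitative trait model
#'
#' Resolves per-QTL minor alleles and genotypic values against a haplotype
#' pool and checks that the variance decomposition is feasible
#' (`sum_j V_P * f_j + V_poly <= V_P`).
#'
#' @param pool A `haplotype_pool`.
#' @param qtl_sites Integer site indices of the QTL.
#' @param mode Inheritance mode shared by all QTL.
#' @param V_P Total phenotypic variance (> 0).
#' @param f Per-QTL variance fractions (scalar recycled).
#' @param V_poly Polygenic variance (>= 0).
#' @param mu General mean of the trait, before genotypic displacement (the
#'   population mean of `Y` also includes the mean of the `mu_j`, which is
#'   nonzero unless allele frequencies are 0.5).
#' @param literal_gj_noise Compatibility switch: add per-individual
#'   `N(0, V_Pj)` noise around each genotype mean.  Off by default because
#'   it double-counts the per-QTL variance (total variance then exceeds
#'   `V_P`); the default reading takes `V_Pj` as the population variance
#'   induced by the genotype frequencies, which the genotypic-value
#'   formulas already guarantee.
#' @return A `qtl_spec`.
#' @export
qtl_spec <- function(pool, qtl_sites,
                     mode = c("additive", "dominant", "recessive"),
                     V_P = 1, f = numeric(0), V_poly = 0, mu = 0,
                     literal_gj_noise = FALSE) {
  mode <- match.arg(mode)
  M <- length(qtl_sites)
  if (M > 0 && any(qtl_sites < 1 | qtl_sites > n_sites(pool))) {
    stop("QTL site index out of range")
  }
  f <- rep_len(f, M)
  if (any(f < 0 | f >= 1)) stop("variance fractions must lie in [0, 1)")
  if (V_poly < 0) stop("V_poly must be non-negative")
  V_Pj <- V_P * f
  V_E <- V_P - sum(V_Pj) - V_poly
  if (V_E < 0) {
    stop(sprintf("variance decomposition infeasible: sum(V_Pj) + V_poly = %.4g > V_P = %.4g",
                 sum(V_Pj) + V_poly, V_P))
  }
  daf <- if (M > 0) allele_frequency(pool, qtl_sites) else numeric(0)
  # A1 is the minor allele; ties (freq 0.5) break toward the derived allele
  a1_is_derived <- daf <= 0.5
  p <- ifelse(a1_is_derived, daf, 1 - daf)
  a <- if (M > 0) {
    vapply(seq_len(M), function(j) genotypic_value(V_P, f[j], p[j], mode),
           numeric(1))
  } else {
    numeric(0)
  }
  structure(
    list(qtl_sites = qtl_sites, mode = mode, V_P = V_P, f = f,
         V_Pj = V_Pj, V_poly = V_poly, V_E = V_E, mu = mu,
         a1_is_derived = a1_is_derived, p = p, a = a,
         literal_gj_noise = literal_gj_noise),
    class = "qtl_spec"
  )
}

#' @export
print.qtl_spec <- function(x, ...) {
  cat(sprintf("<qtl_spec> %d QTL, %s mode, V_P = %g, V_poly = %g, V_E = %g\n",
              length(x$qtl_sites), x$mode, x$V_P, x$V_poly, x$V_E))
  invisible(x)
}

# derived-allele counts at the QTL -> A1 (minor allele) counts
a1_counts <- function(spec, derived_counts) {
  if (!is.matrix(derived_counts)) derived_counts <- matrix(derived_counts, nrow = 1)
  flip <- !spec$a1_is_derived
  if (any(flip)) derived_counts[, flip] <- 2L - derived_counts[, flip]
  derived_counts
}

#' Sample trait values
#'
#' `Y = mu + sum_j mu_j(genotype_j) + N(0, V_poly) + N(0, V_E)`, drawn in a
#' keyed substream of `seed`.
#'
#' @param spec A `qtl_spec`.
#' @param derived_counts Matrix of derived-allele counts at the QTL sites
#'   (individuals in rows).
#' @param seed Integer seed.
#' @return Numeric vector of trait values.
#' @export
sample_trait <- function(spec, derived_counts, seed = 1L) {
  if (!is.matrix(derived_counts)) derived_counts <- matrix(derived_counts, nrow = 1)
  n <- nrow(derived_counts)
  g <- if (length(spec$qtl_sites) > 0) {
    mu_j <- locus_mean(a1_counts(spec, derived_counts), 1, spec$mode)
    mu_j <- sweep(mu_j, 2, spec$a, `*`)
    rowSums(mu_j)
  } else {
    numeric(n)
  }
  with_substream(seed, 23L, {
    if (isTRUE(spec$literal_gj_noise) && length(spec$qtl_sites) > 0) {
      for (j in seq_along(spec$qtl_sites)) {
        g <- g + stats::rnorm(n, 0, sqrt(spec$V_Pj[j]))
      }
    }
    spec$mu + g +
      stats::rnorm(n, 0, sqrt(spec$V_poly)) +
      stats::rnorm(n, 0, sqrt(spec$V_E))
  })
}
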