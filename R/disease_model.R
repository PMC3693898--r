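# Dichotomous disease models.
#
# Model "logistic" (prevalence-driven): P(affected | X) = expit(alpha + B.X)
# where X is the coded genotype vector at the causal loci and alpha either
# is supplied directly or is solved by bisection so that the population
# prevalence matches a target K.
#
# Model "par" (population-attributable-risk):
#   P(affected | X) = f0 * prod(GRR_i^k_i) / (1 - f0 + f0 * prod(GRR_i^k_i))
# with GRR_i = PAR_i / ((1 - PAR_i) * R_i) + 1, R_i the risk allele
# frequency.  This is the same logistic form with alpha = logit(f0) and
# beta_i = log(GRR_i); protective loci use 1/GRR_i.

expit <- stats::plogis
logit <- stats::qlogis

# penetrance evaluation counter, used to verify that the fast case sampler
# never consults the penetrance function after the pilot stage
.pen_env <- new.env(parent = emptyenv())
.pen_env$count <- 0

reset_penetrance_count <- function() .pen_env$count <- 0
penetrance_count <- function() .pen_env$count

#' Code a genotype under an inheritance mode
#'
#' The coded value `k` is the number of mutant (risk) alleles (0, 1, 2)
#' under the additive model, presence/absence of a mutant allele (2/0)
#' under the dominant model, and presence/absence of the homozygous mutant
#' genotype (2/0) under the recessive model.  The same coding drives both
#' disease models, so a log odds ratio has the same per-unit meaning in
#' each.
#'
#' @param count Risk-allele count(s) in `{0, 1, 2}` (vector or matrix).
#' @param mode `"additive"`, `"dominant"` or `"recessive"`.
#' @return Coded value(s) in `{0, 1, 2}`, same shape as `count`.
#' @export
genotype_code <- function(count, mode = c("additive", "dominant", "recessive")) {
  mode <- match.arg(mode)
  if (any(!count %in% c(0L, 1L, 2L))) stop("allele counts must be 0, 1 or 2")
  out <- switch(mode,
    additive  = count,
    dominant  = 2L * (count >= 1L),
    recessive = 2L * (count == 2L)
  )
  if (is.matrix(count)) dim(out) <- dim(count)
  out
}

#' Logistic penetrance
#'
#' `P(affected | X) = exp(alpha + B.X) / (1 + exp(alpha + B.X))`.  With all
#' coded genotypes zero this is `expit(alpha)`, the baseline penetrance f0.
#'
#' @param X Coded genotype vector, or a matrix with one row per individual.
#' @param alpha Intercept (log odds of the baseline penetrance).
#' @param beta Per-locus log odds ratios, length = number of loci.
#' @return Penetrance(s) in (0, 1).
#' @export
penetrance_logistic <- function(X, alpha, beta) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(beta)) stop("length of beta must match loci in X")
  .pen_env$count <- .pen_env$count + nrow(X)
  drop(expit(alpha + X %*% beta))
}

#' PAR-model penetrance
#'
#' `P(affected | X) = f0 * prod(GRR_i^k_i) / (1 - f0 + f0 * prod(GRR_i^k_i))`,
#' algebraically a logistic penetrance with intercept `logit(f0)` and
#' slopes `log(GRR_i)`.  With all `k = 0` it returns exactly `f0`.
#'
#' @param k Coded genotype vector (or matrix, individuals in rows).
#' @param f0 Baseline penetrance in (0, 1).
#' @param grr Per-locus genotype relative risks (> 0); protective loci pass
#'   the inverted value `1/GRR`.
#' @return Penetrance(s) in (0, 1).
#' @export
penetrance_par <- function(k, f0, grr) {
  if (f0 <= 0 || f0 >= 1) stop("f0 must lie in (0, 1)")
  if (any(grr <= 0)) stop("GRR values must be positive")
  penetrance_logistic(k, logit(f0), log(grr))
}

#' Convert a per-locus PAR into a genotype relative risk
#'
#' `GRR_i = PAR_i / ((1 - PAR_i) * R_i) + 1`, where `R_i` is the risk
#' allele frequency.  Rarer variants get larger relative risks when all
#' loci carry equal PAR.
#'
#' @param par_i Population attributable risk(s) in `[0, 1)`.
#' @param risk_freq Risk allele frequency(ies) in (0, 1).
#' @return GRR value(s), always >= 1.
#' @export
par_to_grr <- function(par_i, risk_freq) {
  if (any(par_i < 0 | par_i >= 1)) stop("PAR must lie in [0, 1)")
  if (any(risk_freq <= 0 | risk_freq >= 1)) {
    stop("risk allele frequency must lie in (0, 1)")
  }
  par_i / ((1 - par_i) * risk_freq) + 1
}

#' Split a total PAR across loci
#'
#' `"equal"` gives every locus `par_total / n`; `"random"` draws a uniform
#' point on the simplex (symmetric Dirichlet with concentration 1) scaled
#' to `par_total`.  The per-locus values always sum to the total.
#'
#' @param par_total Overall PAR in `[0, 1)`.
#' @param n Number of loci (>= 1).
#' @param scheme `"equal"` or `"random"`.
#' @param seed Integer seed (random scheme).
#' @return Numeric vector of length `n` summing to `par_total`.
#' @export
split_par <- function(par_total, n, scheme = c("equal", "random"), seed = 1L) {
  scheme <- match.arg(scheme)
  if (par_total < 0 || par_total >= 1) stop("par_total must lie in [0, 1)")
  if (n < 1) stop("n must be >= 1")
  if (scheme == "equal") {
    rep(par_total / n, n)
  } else {
    g <- with_substream(seed, 11L, stats::rexp(n))
    par_total * g / sum(g)
  }
}

#' Flag loci as risk or protective
#'
#' Exactly `round(proportion_risk * n)` loci, chosen uniformly, are flagged
#' as risk; the rest are protective (their GRR is inverted in the PAR
#' model).
#'
#' @param n Number of loci.
#' @param proportion_risk Proportion of risk loci in `[0, 1]`.
#' @param seed Integer seed.
#' @return Logical vector, `TRUE` = risk.
#' @export
assign_risk_flags <- function(n, proportion_risk = 1, seed = 1L) {
  if (proportion_risk < 0 || proportion_risk > 1) {
    stop("proportion_risk must lie in [0, 1]")
  }
  k <- round(proportion_risk * n)
  flags <- rep(FALSE, n)
  if (k > 0) {
    flags[with_substream(seed, 13L, sample.int(n, k))] <- TRUE
  }
  flags
}

#' Specify a dichotomous disease model
#'
#' Builds a fully parameterized disease specification against a haplotype
#' pool.  For the logistic model supply `beta` plus either `alpha` or a
#' target prevalence `K` (in which case [solve_alpha()] calibrates the
#' intercept).  For the PAR model supply `f0` plus one of `par_total`
#' (split across loci by `par_scheme`), `par_per_locus`, or `fixed_grr`.
#'
#' The risk allele is the derived allele by default; `risk_allele =
#' "minor"` instead takes each locus's minor allele as the risk allele.
#'
#' @param pool A `haplotype_pool`.
#' @param causal_sites Integer site indices of the causal loci.
#' @param model `"logistic"` or `"par"`.
#' @param mode Inheritance mode for [genotype_code()].
#' @param beta Log odds ratios (logistic), scalar recycled.
#' @param K Target prevalence in (0, 1) (logistic; triggers alpha search
#'   unless `alpha` is given).
#' @param alpha Logistic intercept, if supplied directly.
#' @param epsilon Alpha-search tolerance on `|K_hat - K|` (default 0.001).
#' @param f0 Baseline penetrance (PAR model).
#' @param par_total Overall PAR in `[0, 1)`.
#' @param par_scheme `"equal"` or `"random"` split of `par_total`.
#' @param par_per_locus Explicit per-locus PAR values (overrides
#'   `par_total`).
#' @param fixed_grr Single GRR applied to every locus (overrides PAR).
#' @param proportion_risk Proportion of risk (vs protective) loci.
#' @param risk_flags Explicit logical risk flags (overrides
#'   `proportion_risk`).
#' @param risk_allele `"derived"` or `"minor"`.
#' @param compat_dominant_het_k1 Compatibility switch: code dominant-model
#'   heterozygotes as `k = 1` instead of the default `k = 2`.
#' @param seed Seed for the random PAR split and risk-flag draw.
#' @return A `disease_spec`.
#' @export
disease_spec <- function(pool, causal_sites,
                         model = c("logistic", "par"),
                         mode = c("additive", "dominant", "recessive"),
                         beta = NULL, K = NULL, alpha = NULL,
                         epsilon = 0.001,
                         f0 = NULL, par_total = NULL,
                         par_scheme = c("equal", "random"),
                         par_per_locus = NULL, fixed_grr = NULL,
                         proportion_risk = 1, risk_flags = NULL,
                         risk_allele = c("derived", "minor"),
                         compat_dominant_het_k1 = FALSE,
                         seed = 1L) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  par_scheme <- match.arg(par_scheme)
  risk_allele <- match.arg(risk_allele)
  n <- length(causal_sites)
  if (n > 0 && any(causal_sites < 1 | causal_sites > n_sites(pool))) {
    stop("causal site index out of range")
  }
  daf <- if (n > 0) allele_frequency(pool, causal_sites) else numeric(0)
  risk_is_derived <- if (risk_allele == "derived") {
    rep(TRUE, n)
  } else {
    daf <= 0.5  # ties broken toward the derived allele
  }
  risk_freq <- ifelse(risk_is_derived, daf, 1 - daf)

  spec <- list(
    causal_sites = causal_sites, model = model, mode = mode,
    risk_is_derived = risk_is_derived, risk_freq = risk_freq,
    epsilon = epsilon, compat_dominant_het_k1 = compat_dominant_het_k1
  )

  if (model == "logistic") {
    if (is.null(beta)) stop("logistic model requires beta")
    beta <- rep_len(beta, n)
    if (is.null(alpha) == is.null(K)) {
      stop("supply exactly one of alpha or K for the logistic model")
    }
    spec$beta <- beta
    spec$K <- K
    spec$alpha <- alpha
  } else {
    if (is.null(f0) || f0 <= 0 || f0 >= 1) stop("PAR model requires f0 in (0, 1)")
    if (is.null(risk_flags)) {
      risk_flags <- assign_risk_flags(n, proportion_risk, seed = seed)
    }
    if (length(risk_flags) != n) stop("risk_flags length mismatch")
    if (!is.null(fixed_grr)) {
      if (fixed_grr < 1) stop("fixed_grr must be >= 1")
      grr <- rep(fixed_grr, n)
      par_i <- NULL
    } else {
      if (is.null(par_per_locus)) {
        if (is.null(par_total)) stop("PAR model requires par_total, par_per_locus or fixed_grr")
        par_i <- split_par(par_total, n, par_scheme, seed = seed)
      } else {
        if (length(par_per_locus) != n) stop("par_per_locus length mismatch")
        par_i <- par_per_locus
      }
      grr <- par_to_grr(par_i, risk_freq)
    }
    spec$f0 <- f0
    spec$par_per_locus <- par_i
    spec$grr <- grr
    spec$risk_flags <- risk_flags
  }
  structure(spec, class = "disease_spec")
}

#' @export
print.disease_spec <- function(x, ...) {
  cat(sprintf("<disease_spec> %s model, %s mode, %d causal locus/loci\n",
              x$model, x$mode, length(x$causal_sites)))
  invisible(x)
}

# derived-allele counts -> risk-allele counts under the spec's convention
risk_counts <- function(spec, derived_counts) {
  if (length(spec$causal_sites) == 0) return(derived_counts)
  flip <- !spec$risk_is_derived
  if (any(flip)) {
    derived_counts[, flip] <- 2L - derived_counts[, flip]
  }
  derived_counts
}

code_spec_genotypes <- function(spec, derived_counts) {
  if (!is.matrix(derived_counts)) {
    derived_counts <- matrix(derived_counts, nrow = 1)
  }
  k <- genotype_code(risk_counts(spec, derived_counts), spec$mode)
  if (spec$mode == "dominant" && isTRUE(spec$compat_dominant_het_k1)) {
    het <- risk_counts(spec, derived_counts) == 1L
    k[het] <- 1L
  }
  k
}

#' Penetrance of individuals under a disease specification
#'
#' @param spec A `disease_spec` with its intercept resolved (logistic model
#'   needs `alpha`; use [solve_alpha()] first when driving by prevalence).
#' @param derived_counts Matrix of derived-allele counts at the causal
#'   sites (individuals in rows), or a single vector.
#' @return Vector of penetrances.
#' @export
penetrance <- function(spec, derived_counts) {
  k <- code_spec_genotypes(spec, derived_counts)
  if (spec$model == "logistic") {
    if (is.null(spec$alpha)) {
      stop("alpha not set; run solve_alpha() or supply alpha directly")
    }
    penetrance_logistic(k, spec$alpha, spec$beta)
  } else {
    grr_eff <- ifelse(spec$risk_flags, spec$grr, 1 / spec$grr)
    penetrance_par(k, spec$f0, grr_eff)
  }
}

# draw coded causal genotypes for n random-mating individuals
draw_causal_counts <- function(pool, causal_sites, n) {
  h1 <- sample.int(n_haplotypes(pool), n, replace = TRUE)
  h2 <- sample.int(n_haplotypes(pool), n, replace = TRUE)
  m <- pool$matrix[, causal_sites, drop = FALSE]
  m[h1, , drop = FALSE] + m[h2, , drop = FALSE]
}

#' Solve the logistic intercept for a target prevalence
#'
#' Bisection over `alpha` in `[-20, 20]`.  The prevalence estimate
#' `K_hat(alpha)` is the mean penetrance over a single fixed Monte Carlo
#' sample of `n_mc` random-mating genotype draws (two pool haplotypes with
#' replacement), reused across iterations, so `K_hat` is a deterministic,
#' continuous, strictly increasing function of `alpha` and bisection
#' terminates with `|K_hat(alpha) - K| < epsilon`.
#'
#' @param pool A `haplotype_pool`.
#' @param spec A logistic `disease_spec`.
#' @param K Target prevalence in (0, 1); defaults to `spec$K`.
#' @param epsilon Stopping tolerance (defaults to `spec$epsilon`).
#' @param n_mc Monte Carlo genotype draws (default 200000, so the sampling
#'   error of `K_hat` is well below the default epsilon for K near 0.1).
#' @param seed Integer seed for the genotype sample.
#' @return The solved `alpha`, with attributes `K_hat` (prevalence at the
#'   solution, on the search sample) and `iterations`.
#' @export
solve_alpha <- function(pool, spec, K = spec$K, epsilon = spec$epsilon,
                        n_mc = 200000L, seed = 1L) {
  if (spec$model != "logistic") stop("alpha search applies to the logistic model")
  if (is.null(K) || K <= 0 || K >= 1) stop("target prevalence K must lie in (0, 1)")
  if (epsilon <= 0) stop("epsilon must be positive")
  counts <- with_substream(seed, 17L,
    draw_causal_counts(pool, spec$causal_sites, n_mc))
  X <- code_spec_genotypes(spec, counts)
  xb <- drop(X %*% spec$beta)
  k_hat <- function(a) mean(expit(a + xb))
  lo <- -20; hi <- 20
  k_lo <- k_hat(lo); k_hi <- k_hat(hi)
  if (K < k_lo - epsilon || K > k_hi + epsilon) {
    stop(sprintf(
      "target prevalence %.6g unreachable: K_hat(-20) = %.3g, K_hat(20) = %.3g",
      K, k_lo, k_hi))
  }
  iter <- 0L
  repeat {
    mid <- (lo + hi) / 2
    km <- k_hat(mid)
    iter <- iter + 1L
    if (abs(km - K) < epsilon) break
    if (km < K) lo <- mid else hi <- mid
    if (iter > 200L) stop("alpha search failed to converge")
  }
  structure(mid, K_hat = km, iterations = iter)
}

#' Monte Carlo population prevalence under a disease specification
#'
#' Mean penetrance over `n_draws` random-mating individuals (two pool
#' haplotypes drawn with replacement).
#'
#' @param pool A `haplotype_pool`.
#' @param spec A resolved `disease_spec`.
#' @param n_draws Number of individuals to draw.
#' @param seed Integer seed.
#' @return Estimated prevalence, with attribute `se` (Monte Carlo standard
#'   error).
#' @export
population_prevalence <- function(pool, spec, n_draws = 200000L, seed = 1L) {
  counts <- with_substream(seed, 19L,
    draw_causal_counts(pool, spec$causal_sites, n_draws))
  pen <- penetrance(spec, counts)
  structure(mean(pen), se = stats::sd(pen) / sqrt(n_draws))
}
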