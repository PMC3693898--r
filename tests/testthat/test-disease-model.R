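test_that("genotype coding follows the three inheritance modes", {
  expect_equal(genotype_code(0:2, "additive"), 0:2)
  expect_equal(genotype_code(0:2, "dominant"), c(0L, 2L, 2L))
  expect_equal(genotype_code(0:2, "recessive"), c(0L, 0L, 2L))
  m <- matrix(c(0L, 1L, 2L, 1L), 2)
  expect_equal(dim(genotype_code(m, "dominant")), dim(m))
  expect_error(genotype_code(3, "additive"), "0, 1 or 2")
})

test_that("logistic penetrance matches hand-computed values", {
  expect_equal(penetrance_logistic(0, log(0.1 / 0.9), 0.5), 0.1)
  expect_equal(penetrance_logistic(0, 0, 1), 0.5)
  # alpha = ln(1/9), one locus beta = ln 1.5, X = 1:
  # odds = 1.5/9 -> p = (1.5/9)/(1 + 1.5/9) = 1/7
  expect_equal(penetrance_logistic(1, log(1 / 9), log(1.5)), 1 / 7,
               tolerance = 1e-12)
  expect_error(penetrance_logistic(c(1, 0), 0, 1), "match")
})

test_that("PAR-model penetrance matches hand-computed values", {
  expect_equal(penetrance_par(c(0, 0), 0.37, c(2, 3)), 0.37)  # empty product
  expect_equal(penetrance_par(2, 0.1, 2), 0.4 / 1.3, tolerance = 1e-12)
  # protective locus: GRR inverted before the call
  expect_equal(penetrance_par(2, 0.1, 1 / 2), 0.025 / 0.925, tolerance = 1e-12)
  expect_error(penetrance_par(1, 1.2, 2), "f0")
})

test_that("PAR converts to GRR by the stated formula", {
  expect_equal(par_to_grr(0, 0.3), 1)
  expect_equal(par_to_grr(0.05, 0.1), 0.05 / (0.95 * 0.1) + 1)   # 1.5263
  expect_equal(par_to_grr(0.1 / 30, 0.005),
               (0.1 / 30) / ((1 - 0.1 / 30) * 0.005) + 1)        # 1.6689
  expect_equal(round(par_to_grr(0.1 / 30, 0.005), 4), 1.6689)
  # rarer variants get higher GRR at equal PAR
  expect_gt(par_to_grr(0.01, 0.001), par_to_grr(0.01, 0.01))
  expect_error(par_to_grr(0.05, 0), "frequency")
})

test_that("PAR splits preserve the total", {
  eq <- split_par(0.1, 30, "equal")
  expect_equal(eq, rep(0.1 / 30, 30))
  expect_equal(sum(eq), 0.1, tolerance = 1e-12)
  rnd <- split_par(0.1, 4, "random", seed = 9)
  expect_equal(sum(rnd), 0.1, tolerance = 1e-12)
  expect_true(all(rnd >= 0))
  expect_identical(rnd, split_par(0.1, 4, "random", seed = 9))
  expect_false(identical(rnd, split_par(0.1, 4, "random", seed = 10)))
  expect_equal(split_par(0, 5, "random"), rep(0, 5))
  expect_error(split_par(1, 3), "\\[0, 1\\)")
})

test_that("risk/protective flags follow the requested proportion", {
  expect_equal(assign_risk_flags(5, 1), rep(TRUE, 5))
  expect_equal(assign_risk_flags(5, 0), rep(FALSE, 5))
  expect_equal(sum(assign_risk_flags(10, 0.8, seed = 2)), 8)
  expect_identical(assign_risk_flags(10, 0.5, seed = 3),
                   assign_risk_flags(10, 0.5, seed = 3))
})

test_that("alpha search recovers the closed form with no causal loci", {
  pool <- single_site_pool(100, 30)
  spec <- disease_spec(pool, integer(0), model = "logistic",
                       beta = numeric(0), K = 0.1)
  a <- solve_alpha(pool, spec, n_mc = 1000, seed = 1)
  # |expit(a) - 0.1| < 1e-3  =>  a within ~0.012 of logit(0.1)
  expect_lt(abs(as.numeric(a) - log(1 / 9)), 0.02)
  expect_lt(abs(attr(a, "K_hat") - 0.1), 1e-3)
})

test_that("alpha search agrees with a three-genotype root-finding oracle", {
  pool <- single_site_pool(1000, 300)    # derived freq 0.3
  spec <- disease_spec(pool, 1L, model = "logistic", beta = log(2), K = 0.2)
  a <- solve_alpha(pool, spec, n_mc = 200000, seed = 4)
  # independent oracle: prevalence as exact HWE sum over 3 genotypes
  k_exact <- function(alpha) {
    sum(hwe_freqs(0.3) * plogis(alpha + (0:2) * log(2)))
  }
  a_oracle <- uniroot(function(x) k_exact(x) - 0.2, c(-20, 20),
                      tol = 1e-10)$root
  expect_lt(abs(k_exact(as.numeric(a)) - 0.2), 0.005)
  expect_lt(abs(as.numeric(a) - a_oracle), 0.05)
})

test_that("alpha search errors when the target prevalence is unreachable", {
  pool <- single_site_pool(100, 30)
  spec <- disease_spec(pool, 1L, model = "logistic", beta = -50, K = 0.5)
  expect_error(solve_alpha(pool, spec, K = 0.999999, n_mc = 1000),
               "unreachable")
})

test_that("estimated prevalence is monotone in alpha", {
  pool <- single_site_pool(200, 60)
  spec <- disease_spec(pool, 1L, model = "logistic", beta = log(1.5),
                       alpha = 0)
  counts <- seqcohort:::with_substream(5, 17L,
    seqcohort:::draw_causal_counts(pool, 1L, 5000))
  k_hat <- vapply(seq(-6, 2, by = 0.5), function(a) {
    spec$alpha <- a
    mean(penetrance(spec, counts))
  }, numeric(1))
  expect_true(all(diff(k_hat) > 0))
})

test_that("alpha search postcondition holds across random configurations", {
  pool <- generate_block_pool(500, 1, theta_per_block = 20, seed = 21)
  for (i in 1:20) {
    set.seed(300 + i)
    L <- sample(1:4, 1)
    cs <- sample(n_sites(pool), L)
    K <- sample(c(0.05, 0.1, 0.2), 1)
    spec <- disease_spec(pool, cs, model = "logistic",
                         beta = runif(L, log(1.2), log(2)), K = K)
    a <- solve_alpha(pool, spec, n_mc = 50000, seed = i)
    expect_lt(abs(attr(a, "K_hat") - K), 1e-3)
  }
})

test_that("relabeling the risk allele with inverted GRR preserves penetrance", {
  # for every genotype: counting the other allele, inverting GRR, swapping
  # dominant <-> recessive and re-anchoring the baseline at the new
  # reference genotype gives the same penetrance function
  swap_mode <- c(additive = "additive", dominant = "recessive",
                 recessive = "dominant")
  for (mode in c("additive", "dominant", "recessive")) {
    for (g in c(1.5, 2, 4)) {
      f0 <- 0.1
      pen1 <- function(c) {
        penetrance_par(genotype_code(c, mode), f0, g)
      }
      f0_new <- pen1(2)     # baseline of the relabeled model
      pen2 <- function(c) {
        penetrance_par(genotype_code(2 - c, swap_mode[[mode]]), f0_new, 1 / g)
      }
      for (c in 0:2) expect_equal(pen2(c), pen1(c), tolerance = 1e-12)
    }
  }
})

test_that("null PAR model reduces to the baseline penetrance exactly", {
  pool <- single_site_pool(100, 30)
  spec <- disease_spec(pool, 1L, model = "par", f0 = 0.05, par_total = 0)
  k <- population_prevalence(pool, spec, n_draws = 500, seed = 2)
  expect_equal(as.numeric(k), 0.05)
  expect_equal(attr(k, "se"), 0)
})

test_that("Monte Carlo prevalence matches exhaustive pair enumeration", {
  set.seed(8)
  m <- matrix(rbinom(12 * 3, 1, 0.4), 12, 3)
  m[1, ] <- 1L; m[2, ] <- 0L
  pool <- pool_from_matrix(m)
  spec <- disease_spec(pool, 1:3, model = "par", f0 = 0.1, par_total = 0.2)
  # oracle: enumerate all ordered haplotype pairs
  N <- n_haplotypes(pool)
  pairs <- expand.grid(i = 1:N, j = 1:N)
  counts <- pool$matrix[pairs$i, ] + pool$matrix[pairs$j, ]
  k_exact <- mean(penetrance(spec, counts))
  k_mc <- population_prevalence(pool, spec, n_draws = 50000, seed = 5)
  expect_lt(abs(as.numeric(k_mc) - k_exact), 3 * attr(k_mc, "se"))
})

test_that("per-allele odds ratio is recovered from a large case-control sample", {
  pool <- single_site_pool(1000, 300)
  spec <- disease_spec(pool, 1L, model = "logistic", beta = log(1.5), K = 0.1)
  spec$alpha <- as.numeric(solve_alpha(pool, spec, seed = 6))
  cc <- simulate_case_control(pool, spec, 25000, 25000, seed = 7)
  g <- cohort_genotypes(cc, pool, 1L)[, 1]
  y <- as.integer(cc$members$aff == 2L)
  fit <- glm(y ~ g, family = binomial())
  or <- exp(coef(fit)[["g"]])
  expect_lt(abs(or - 1.5) / 1.5, 0.05)
})

test_that("null PAR model leaves case genotype frequencies at pool values", {
  pool <- single_site_pool(400, 80)      # derived freq 0.2
  spec <- disease_spec(pool, 1L, model = "par", f0 = 0.1, par_total = 0)
  cc <- simulate_case_control(pool, spec, 4000, 4000, seed = 9)
  g <- cohort_genotypes(cc, pool, 1L)[, 1]
  for (grp in list(which(cc$members$aff == 2L), which(cc$members$aff == 1L))) {
    f_hat <- mean(g[grp]) / 2
    se <- sqrt(0.2 * 0.8 / (2 * length(grp)))
    expect_lt(abs(f_hat - 0.2), 3 * se)
  }
})
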