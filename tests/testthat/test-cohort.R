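test_that("founder draws reproduce pool allele frequencies", {
  pool <- toy_pool()
  n <- 2e4
  h <- seqcohort:::with_substream(1, 0L, {
    N <- n_haplotypes(pool)
    cb <- seqcohort:::block_chroms(pool)
    b1 <- matrix(0L, n, 2); b2 <- matrix(0L, n, 2)
    for (ch in unique(cb)) {
      b1[, cb == ch] <- sample.int(N, n, replace = TRUE)
      b2[, cb == ch] <- sample.int(N, n, replace = TRUE)
    }
    list(h1 = b1, h2 = b2)
  })
  counts <- seqcohort:::geno_from_haps(pool, h$h1, h$h2, 1:8)
  f_hat <- colMeans(counts) / 2
  f <- pool$sites$freq
  expect_true(all(abs(f_hat - f) < 3 * sqrt(f * (1 - f) / (2 * n))))
})

test_that("draw_founder is deterministic and handles a single-haplotype pool", {
  pool <- toy_pool()
  expect_identical(draw_founder(pool, seed = 4), draw_founder(pool, seed = 4))
  # a 1-haplotype pool cannot be polymorphic; bypass validation on purpose
  one <- seqcohort:::new_haplotype_pool(
    matrix(c(0L, 1L), 1, 2),
    data.frame(chrom = "1", pos_bp = 1:2, block = 1L, freq = c(0, 1)))
  f <- draw_founder(one, seed = 1)
  expect_equal(f$h1, f$h2)
})

test_that("meiosis transmits intact blocks according to the map", {
  pool <- toy_pool()
  parent <- list(h1 = c(3L, 3L), h2 = c(9L, 9L))
  linked <- fixed_map(0, 2)
  g <- meiosis(parent, linked, seed = 2)
  expect_true(identical(g, parent$h1) || identical(g, parent$h2))

  # theta = 0.2: recombinant fraction over many meioses
  rmap <- fixed_map(0.2, 2)
  rec <- seqcohort:::with_substream(3, 0L, {
    mean(replicate(1e4, {
      g <- seqcohort:::meiosis_rows(parent$h1, parent$h2, rmap$theta)
      g[1] != g[2]
    }))
  })
  expect_lt(abs(rec - 0.2), 3 * sqrt(0.2 * 0.8 / 1e4))

  # theta = 0.5: first block is a fair coin
  free <- fixed_map(0.5, 2)
  first <- seqcohort:::with_substream(5, 0L, {
    mean(replicate(4000, seqcohort:::meiosis_rows(parent$h1, parent$h2,
                                                  free$theta)[1] == 3L))
  })
  expect_lt(abs(first - 0.5), 3 * sqrt(0.25 / 4000))
  expect_error(meiosis(list(h1 = 1L, h2 = 2L), rmap), "block count")
})

test_that("a pedigree has 12 members and passes the Mendelian audit", {
  pool <- toy_pool()
  rmap <- fixed_map(0.2, 2)
  spec <- disease_spec(pool, 1L, model = "par", f0 = 0.2, par_total = 0.05)
  ped <- simulate_family(pool, rmap, disease = spec, seed = 10)
  expect_equal(nrow(ped$members), 12)
  expect_equal(ped$members$gen, c(1, 1, 1, 1, 2, 2, rep(3, 6)))
  expect_true(all(ped$members$aff %in% 1:2))
  expect_true(isTRUE(audit_mendelian(ped)))
  expect_identical(ped$hap1,
                   simulate_family(pool, rmap, disease = spec, seed = 10)$hap1)
})

test_that("degenerate penetrance-one model affects every family member", {
  pool <- toy_pool()
  rmap <- fixed_map(0.1, 2)
  spec <- disease_spec(pool, 1L, model = "logistic", beta = 0, alpha = 30)
  ped <- simulate_family(pool, rmap, disease = spec, seed = 3)
  expect_true(all(ped$members$aff == 2L))
})

test_that("trait-only families carry traits but unknown affection", {
  pool <- toy_pool()
  rmap <- fixed_map(0.1, 2)
  qspec <- qtl_spec(pool, 2L, V_P = 1, f = 0.1)
  ped <- simulate_family(pool, rmap, trait = qspec, seed = 6)
  expect_true(all(ped$members$aff == 0L))
  expect_true(all(is.finite(ped$members$trait)))
})

test_that("ascertainment counts affected third-generation siblings", {
  pool <- toy_pool()
  rmap <- fixed_map(0.1, 2)
  spec <- disease_spec(pool, 1L, model = "par", f0 = 0.2, par_total = 0.05)
  ped <- simulate_family(pool, rmap, disease = spec, seed = 10)
  ped$members$aff <- 1L
  expect_false(ascertain(ped, 1))
  ped$members$aff[ped$members$gen == 3][1:2] <- 2L
  ped$members$aff[1] <- 2L     # grandparent affection must not count
  expect_true(ascertain(ped, 2))
  expect_false(ascertain(ped, 3))
})

test_that("ascertained family samples satisfy the sibling rule", {
  pool <- toy_pool()
  rmap <- fixed_map(0.1, 2)
  spec <- disease_spec(pool, 1L, model = "logistic", beta = log(2), alpha = -2)
  coh <- simulate_families(pool, rmap, disease = spec, n_families = 30, s = 2,
                           seed = 11)
  m <- coh$members
  n_aff <- tapply(m$aff == 2L & m$gen == 3L, m$fid, sum)
  expect_true(all(n_aff >= 2))
  expect_equal(length(unique(m$fid)), 30)
  expect_true(isTRUE(audit_mendelian(coh)))
})

test_that("family samples are invariant to the worker count", {
  pool <- toy_pool()
  rmap <- fixed_map(0.1, 2)
  spec <- disease_spec(pool, 1L, model = "logistic", beta = log(2), alpha = -2)
  ref <- simulate_families(pool, rmap, disease = spec, n_families = 12,
                           s = 1, seed = 13, n_workers = 1)
  for (w in c(2L, 8L)) {
    alt <- simulate_families(pool, rmap, disease = spec, n_families = 12,
                             s = 1, seed = 13, n_workers = w)
    expect_identical(alt$members, ref$members)
    expect_identical(alt$hap1, ref$hap1)
    expect_identical(alt$hap2, ref$hap2)
  }
})

test_that("ascertainment acceptance rate matches a brute-force estimate", {
  pool <- toy_pool()
  rmap <- fixed_map(0.1, 2)
  spec <- disease_spec(pool, 1L, model = "logistic", beta = log(1.5),
                       alpha = -2)
  # brute force: raw families without ascertainment
  hits <- vapply(1:400, function(i) {
    ascertain(simulate_family(pool, rmap, disease = spec, seed = 9000 + i), 1)
  }, logical(1))
  p_brute <- mean(hits)
  coh <- simulate_families(pool, rmap, disease = spec, n_families = 150,
                           s = 1, seed = 17)
  p_obs <- attr(coh, "acceptance_rate")
  se <- sqrt(p_brute * (1 - p_brute) * (1 / 400 + 1 / (150 / p_obs)))
  expect_lt(abs(p_obs - p_brute), 4 * se)
})

test_that("random-ascertainment trait families are kept without rejection", {
  pool <- toy_pool()
  rmap <- fixed_map(0.1, 2)
  qspec <- qtl_spec(pool, 2L, V_P = 1, f = 0.1)
  coh <- simulate_families(pool, rmap, trait = qspec, n_families = 8, seed = 19)
  expect_equal(attr(coh, "acceptance_rate"), 1)
  expect_equal(length(unique(coh$members$fid)), 8)
})

test_that("case and control genotype frequencies follow Bayes' rule", {
  pool <- single_site_pool(500, 100)     # derived freq 0.2
  spec <- disease_spec(pool, 1L, model = "par", f0 = 0.1, par_total = 0.1)
  pen_g <- penetrance(spec, matrix(0:2, ncol = 1))
  pg <- hwe_freqs(0.2)
  K <- sum(pg * pen_g)
  p_case <- pg * pen_g / K
  p_ctrl <- pg * (1 - pen_g) / (1 - K)
  cc <- simulate_case_control(pool, spec, 10000, 10000, seed = 23)
  g <- cohort_genotypes(cc, pool, 1L)[, 1]
  obs_case <- tabulate(g[cc$members$aff == 2L] + 1L, 3) / 10000
  obs_ctrl <- tabulate(g[cc$members$aff == 1L] + 1L, 3) / 10000
  for (k in 1:3) {
    expect_lt(abs(obs_case[k] - p_case[k]),
              3 * sqrt(p_case[k] * (1 - p_case[k]) / 10000) + 1e-4)
    expect_lt(abs(obs_ctrl[k] - p_ctrl[k]),
              3 * sqrt(p_ctrl[k] * (1 - p_ctrl[k]) / 10000) + 1e-4)
  }
})

test_that("conditional genotype table is a normalized point estimate", {
  x <- matrix(c(0L, 1L, 0L, 1L, 0L, 1L, 2L, 0L), 4, 2)
  cond <- fit_case_conditional(x)
  expect_equal(sum(cond$prob), 1, tolerance = 1e-12)
  point <- fit_case_conditional(matrix(c(1L, 1L), 2, 1))
  expect_equal(point$prob, 1)
  expect_error(fit_case_conditional(matrix(0L, 0, 2)), "at least one")
})

test_that("fast cases are consistent with their sampled genotype", {
  pool <- single_site_pool(500, 100)
  cond <- fit_case_conditional(matrix(2L, 5, 1))   # hom derived point mass
  fast <- sample_case_fast(cond, pool, 1L, 50, seed = 3)
  g <- pool$matrix[fast$h1[, 1], 1] + pool$matrix[fast$h2[, 1], 1]
  expect_true(all(g == 2L))
})

test_that("fast sampler reproduces the conditional distribution without penetrance calls", {
  pool <- single_site_pool(500, 100)
  spec <- disease_spec(pool, 1L, model = "par", f0 = 0.1, par_total = 0.1)
  pilot <- simulate_cases_rejection(pool, spec, 200, seed = 29)
  pcounts <- seqcohort:::geno_from_haps(pool, pilot$h1, pilot$h2, 1L)
  cond <- fit_case_conditional(pcounts)
  seqcohort:::reset_penetrance_count()
  fast <- sample_case_fast(cond, pool, 1L, 10000, seed = 31)
  expect_equal(seqcohort:::penetrance_count(), 0)
  g <- pool$matrix[fast$h1[, 1], 1] + pool$matrix[fast$h2[, 1], 1]
  obs <- tabulate(g + 1L, 3)
  expected <- vapply(0:2, function(k) {
    i <- which(cond$levels[, 1] == k)
    if (length(i)) cond$prob[i] else 0
  }, numeric(1))
  keep <- expected > 0
  chi <- chisq.test(obs[keep], p = expected[keep])
  expect_gt(chi$p.value, 0.01)
})

test_that("fast and rejection samplers agree with a large pilot", {
  pool <- single_site_pool(500, 100)
  spec <- disease_spec(pool, 1L, model = "par", f0 = 0.1, par_total = 0.1)
  pilot <- simulate_cases_rejection(pool, spec, 10000, seed = 37)
  pcounts <- seqcohort:::geno_from_haps(pool, pilot$h1, pilot$h2, 1L)
  cond <- fit_case_conditional(pcounts)
  fast <- sample_case_fast(cond, pool, 1L, 10000, seed = 41)
  rej <- simulate_cases_rejection(pool, spec, 10000, seed = 43)
  gf <- pool$matrix[fast$h1[, 1], 1] + pool$matrix[fast$h2[, 1], 1]
  gr <- pool$matrix[rej$h1[, 1], 1] + pool$matrix[rej$h2[, 1], 1]
  tab <- rbind(tabulate(gf + 1L, 3), tabulate(gr + 1L, 3))
  chi <- suppressWarnings(chisq.test(tab[, colSums(tab) > 0]))
  expect_gt(chi$p.value, 0.01)
})

test_that("faithful third-generation sampling matches the founder shortcut", {
  pool <- toy_pool()
  rmap <- fixed_map(0.3, 2)
  spec <- disease_spec(pool, 1L, model = "par", f0 = 0.3, par_total = 0.05)
  short <- simulate_cases_rejection(pool, spec, 3000, seed = 47)
  faith <- simulate_cases_rejection(pool, spec, 3000, seed = 53, rmap = rmap,
                                    faithful_thirdgen = TRUE)
  f_short <- colMeans(seqcohort:::geno_from_haps(pool, short$h1, short$h2, 1:8)) / 2
  f_faith <- colMeans(seqcohort:::geno_from_haps(pool, faith$h1, faith$h2, 1:8)) / 2
  expect_true(all(abs(f_short - f_faith) < 4 * sqrt(0.5 * 0.5 / 3000)))
})

test_that("case-control cohorts label and structure individuals correctly", {
  pool <- single_site_pool(500, 100)
  spec <- disease_spec(pool, 1L, model = "par", f0 = 0.1, par_total = 0.1)
  cc <- simulate_case_control(pool, spec, 30, 20, fast_mode = TRUE,
                              pilot_cases = 50, seed = 59)
  m <- cc$members
  expect_equal(nrow(m), 50)
  expect_equal(sum(m$aff == 2L), 30)
  expect_true(all(m$pat == 0L & m$mat == 0L))
  expect_false(any(duplicated(paste(m$fid, m$iid))))
  expect_identical(
    cc$hap1,
    simulate_case_control(pool, spec, 30, 20, fast_mode = TRUE,
                          pilot_cases = 50, seed = 59)$hap1)
})
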