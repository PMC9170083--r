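test_that("configuration validation rejects malformed inputs", {
  pool <- list(B = c("B*01:01" = 0.5, "B*02:01" = 0.5))
  expect_error(generator_config(10, "B", allele_pool = list(B = numeric()),
                                mu_locus = c(B = 1)), "empty allele pool")
  expect_error(generator_config(10, "B",
                                allele_pool = list(B = c("x" = 0.6, "y" = 0.5)),
                                mu_locus = c(B = 1)), "sum to 1")
  expect_error(generator_config(10, "B", allele_pool = pool,
                                mu_locus = c(B = 1), sigma_A = -1), "non-negative")
  expect_error(generator_config(-1, "B", allele_pool = pool, mu_locus = c(B = 1)),
               "non-negative integer")
  expect_error(generator_config(10, "B", allele_pool = pool, mu_locus = c(B = 1),
                                sigma_H = 0.2), "haplotype_table")
  ht <- data.frame(B = c("B*01:01", "B*02:01"), freq = c(0.7, 0.3))
  mk <- data.frame(chrom = "6", pos = c(100, 100), ref = "A", alt = "G")
  expect_error(generator_config(10, "B", allele_pool = pool, mu_locus = c(B = 1),
                                haplotype_table = ht, markers = mk,
                                marker_alleles = matrix(0, 2, 2)),
               "strictly increasing")
})

test_that("empty cohorts and determinism contracts hold", {
  cfg <- one_locus_config(seed = 5, n = 0)
  coh <- sample_cohort(cfg)
  expect_length(coh$sample_ids, 0)
  expect_length(coh$allele_effects, 0)
  expect_equal(nrow(simulate_expression(coh, "unstim")), 0)

  cfg <- one_locus_config(seed = 11)
  c1 <- sample_cohort(cfg)
  c2 <- sample_cohort(cfg)
  expect_identical(c1, c2)
  expect_identical(simulate_expression(c1, "unstim"),
                   simulate_expression(c2, "unstim"))
  # conditions share the allele assignment but draw fresh residuals
  e_u <- simulate_expression(c1, "unstim")
  e_f <- simulate_expression(c1, "fresh")
  expect_identical(e_u$allele, e_f$allele)
  expect_false(any(e_u$tpm == e_f$tpm))
})

test_that("degenerate variances give exactly deterministic tpm", {
  cfg <- one_locus_config(seed = 2, n = 20, sigma_A = 0, sigma_G = 0,
                          sigma_E = 0, mu = log(1000))
  expr <- simulate_expression(sample_cohort(cfg), "unstim")
  expect_equal(expr$tpm, rep(1000, nrow(expr)), tolerance = 1e-12)

  # stimulation shift is exactly multiplicative in the degenerate case
  cfg2 <- one_locus_config(seed = 2, n = 10, sigma_A = 0, sigma_G = 0,
                           sigma_E = 0, mu = log(1000),
                           stim_logfold = c(B = log(2)))
  coh2 <- sample_cohort(cfg2)
  expect_equal(simulate_expression(coh2, "stim")$tpm, rep(2000, 20),
               tolerance = 1e-12)
})

test_that("planted eQTL effects are exactly additive on the ln scale", {
  b <- 0.4
  ht <- data.frame(B = c("B*01:01", "B*02:01"), freq = c(0.5, 0.5),
                   stringsAsFactors = FALSE)
  mk <- data.frame(chrom = "6", pos = 31243785L, ref = "G", alt = "T",
                   stringsAsFactors = FALSE)
  ma <- matrix(c(1, 0), 2, 1)  # variant rides on haplotype 1 only
  cfg <- generator_config(
    n_individuals = 200, loci = "B",
    allele_pool = list(B = c("B*01:01" = 0.5, "B*02:01" = 0.5)),
    haplotype_table = ht, mu_locus = c(B = log(1000)),
    sigma_A = 0, sigma_G = 0, sigma_E = 0,
    markers = mk, marker_alleles = ma,
    eqtl_specs = data.frame(marker_id = "6:31243785:G:T", locus = "B",
                            beta = b),
    seed = 3)
  coh <- sample_cohort(cfg)
  gm <- simulate_genotypes(coh)
  expr <- simulate_expression(coh, "unstim")
  mean_ln <- tapply(log(expr$tpm), gm$dosages[expr$sample_id, 1], mean)
  expect_equal(unname(mean_ln["2"] - mean_ln["0"]), 2 * b, tolerance = 1e-12)
})

test_that("realized haplotype frequencies track nominal ones", {
  ht <- data.frame(A = c("A*01:01", "A*02:01", "A*03:01"),
                   freq = c(0.6, 0.3, 0.1), stringsAsFactors = FALSE)
  cfg <- generator_config(50000, "A",
                          allele_pool = list(A = c("A*01:01" = 1/3, "A*02:01" = 1/3,
                                                   "A*03:01" = 1/3)),
                          haplotype_table = ht, mu_locus = c(A = 1), seed = 21)
  coh <- sample_cohort(cfg)
  realized <- tabulate(c(coh$hap1, coh$hap2), 3) / (2 * 50000)
  expect_true(all(abs(realized - ht$freq) < 0.01))
})

test_that("locus mean tpm matches the lognormal-corrected target", {
  # oracle applies the exp(sigma^2/2) lognormal mean correction
  sig <- c(A = 0.10, G = 0.20, E = 0.08)
  cfg <- one_locus_config(seed = 8, n = 5000, sigma_A = sig["A"],
                          sigma_G = sig["G"], sigma_E = sig["E"],
                          mu = log(1870), mode = "fresh")
  expr <- simulate_expression(sample_cohort(cfg), "unstim")
  expected <- 1870 * exp(sum(sig^2) / 2)
  expect_equal(mean(expr$tpm), expected, tolerance = 0.02)
})

test_that("genotypes are haplotype sums with LD from haplotype sharing", {
  ht <- data.frame(B = c("B*01:01", "B*02:01"), freq = c(0.5, 0.5),
                   stringsAsFactors = FALSE)
  mk <- data.frame(chrom = "6", pos = c(100L, 200L, 300L, 400L), ref = "A",
                   alt = "G", stringsAsFactors = FALSE)
  # founder marker vectors (1,0,.,.) and (1,1,.,.); markers 3 and 4
  # identical across founders; marker 1 carried by every founder
  ma <- rbind(c(1, 0, 1, 1), c(1, 1, 0, 0))
  cfg <- generator_config(500, "B",
                          allele_pool = list(B = c("B*01:01" = .5, "B*02:01" = .5)),
                          haplotype_table = ht, mu_locus = c(B = 1),
                          markers = mk, marker_alleles = ma, seed = 4)
  coh <- sample_cohort(cfg)
  gm <- simulate_genotypes(coh)
  expect_equal(unname(gm$dosages[, 2]),
               unname(ma[coh$hap1, 2] + ma[coh$hap2, 2]))
  expect_true(all(gm$dosages[, 1] == 2))  # on all founders -> monomorphic
  expect_equal(ld_r2(gm, gm$variants$id[3], gm$variants$id[4]), 1)

  # one individual with founder marker vectors (1,0),(1,1) -> dosages (2,1)
  i <- which(coh$hap1 == 1 & coh$hap2 == 2)[1]
  expect_equal(unname(gm$dosages[i, c(1, 2)]), c(2, 1))
})

test_that("the individual factor cancels in the ASE distribution", {
  a1 <- het_ase_draws(5000, sigma_A = 0.10, sigma_E = 0.08, seed = 31,
                      sigma_G = 0)
  a2 <- het_ase_draws(5000, sigma_A = 0.10, sigma_E = 0.08, seed = 32,
                      sigma_G = 5)
  ks <- suppressWarnings(stats::ks.test(a1, a2))
  expect_gt(ks$p.value, 0.01)
})

test_that("allele-pair rank correlation increases with the shared factor", {
  rho_at <- function(sg) {
    cfg <- one_locus_config(seed = 77, n = 5000, n_alleles = 30, sigma_G = sg)
    expr <- simulate_expression(sample_cohort(cfg), "unstim")
    spearman_allele_pairs(expr, "B", "unstim")$rho
  }
  rhos <- vapply(c(0, 0.2, 0.4), rho_at, numeric(1))
  expect_true(all(diff(rhos) > 0))
})

test_that("median ASE follows the half-normal closed form", {
  a <- het_ase_draws(100000, sigma_A = 0.10, sigma_E = 0.08, seed = 12)
  expect_lt(abs(median(a) - ase_median_closed_form(0.10, 0.08)), 0.005)
})
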