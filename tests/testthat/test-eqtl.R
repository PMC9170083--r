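test_that("HWE chi-square hits its closed-form landmarks", {
  expect_equal(hwe_test(25, 50, 25), 1)           # exact HWE proportions
  expect_equal(hwe_test(50, 0, 50), pchisq(100, 1, lower.tail = FALSE))
  expect_equal(hwe_test(100, 0, 0), 1)            # monomorphic
  expect_error(hwe_test(-1, 0, 5), "non-negative")
  expect_error(hwe_test(0, 0, 0), "total count")
})

test_that("HWE chi-square agrees with exact enumeration in its valid regime", {
  set.seed(51)
  checked <- 0
  for (i in 1:300) {
    n <- sample(50:200, 1)
    f <- runif(1, 0.15, 0.85)
    g <- sample(0:2, n, TRUE, c(f^2, 2 * f * (1 - f), (1 - f)^2))
    cnt <- tabulate(g + 1, 3)
    phat <- (2 * cnt[1] + cnt[2]) / (2 * n)
    if (min(n * c(phat^2, 2 * phat * (1 - phat), (1 - phat)^2)) < 5) next
    pe <- hwe_exact_oracle(cnt[1], cnt[2], cnt[3])
    if (pe <= 1e-4) next
    pc <- hwe_test(cnt[1], cnt[2], cnt[3])
    expect_lt(pc / pe, 2)
    expect_gt(pc / pe, 0.5)
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("variant QC filters by MAF, missingness and HWE with a fate log", {
  n <- 400
  set.seed(33)
  gm <- random_genotypes(n, 4, maf = c(0.3, 0.3, 0.3, 0.3))
  gm$dosages[, 1] <- c(rep(1, 4), rep(0, n - 4))        # MAF 0.005
  gm$dosages[1:15, 2] <- NA                             # missingness 0.0375
  gm$dosages[, 3] <- rep(c(0, 2), n / 2)                # het deficit
  qc <- qc_filter_variants(gm)
  expect_equal(qc$log$fate, c("maf", "missing", "hwe", "pass"))
  expect_equal(qc$genotypes$variants$id, gm$variants$id[4])

  # surviving set equals the independent per-rule oracle intersection
  set.seed(34)
  gm2 <- random_genotypes(300, 100, maf = runif(100, 0.002, 0.5))
  gm2$dosages[sample(length(gm2$dosages), 900)] <- NA
  qc2 <- qc_filter_variants(gm2)
  keep_oracle <- vapply(seq_len(100), function(j) {
    d <- gm2$dosages[, j]
    ok <- !is.na(d)
    af <- mean(d[ok]) / 2
    min(af, 1 - af) >= 0.01 && mean(!ok) <= 0.025 &&
      hwe_exact_oracle(sum(d[ok] == 0), sum(d[ok] == 1), sum(d[ok] == 2)) >= 1e-7
  }, logical(1))
  # oracle uses the chi-square rule for the HWE leg to stay comparable
  keep_chi <- vapply(seq_len(100), function(j) {
    d <- gm2$dosages[, j]
    ok <- !is.na(d)
    af <- mean(d[ok]) / 2
    min(af, 1 - af) >= 0.01 && mean(!ok) <= 0.025 &&
      hwe_test(sum(d[ok] == 0), sum(d[ok] == 1), sum(d[ok] == 2)) >= 1e-5
  }, logical(1))
  expect_equal(qc2$genotypes$variants$id, gm2$variants$id[keep_chi])

  # idempotence
  qc3 <- qc_filter_variants(qc2$genotypes)
  expect_equal(dim(qc3$genotypes), dim(qc2$genotypes))
  expect_true(all(qc3$log$fate == "pass"))
})

test_that("inverse normal transform maps ranks to normal quantiles", {
  got <- inverse_normal_transform(c(5, 1, 9))
  expect_equal(got, qnorm(c(3, 1, 5) / 6))
  x <- rexp(500)
  expect_equal(inverse_normal_transform(x), inverse_normal_transform(log(x)))
  y <- inverse_normal_transform(x)
  expect_lt(abs(mean(y)), 0.01)
  expect_equal(sd(y), 1, tolerance = 0.01)
  expect_error(inverse_normal_transform(rep(1, 5)), "distinct")
})

test_that("residualization matches the normal equations", {
  set.seed(71)
  y <- rnorm(50)
  x <- scale(rnorm(50))  # centered, orthogonal to intercept by centering
  expect_equal(residualize(y, NULL), y - mean(y))
  expect_equal(residualize(as.numeric(x), cbind(as.numeric(x))),
               rep(0, 50), tolerance = 1e-12)
  Z <- matrix(rnorm(150), 50, 3)
  X <- cbind(1, Z)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize(y, Z), as.numeric(y - X %*% beta), tolerance = 1e-10)
  expect_error(residualize(y, cbind(Z, Z[, 1])), "rank deficient")
})

test_that("principal components recover planted directions", {
  set.seed(91)
  n <- 100
  u1 <- rnorm(n, sd = 5); u2 <- rnorm(n, sd = 2)
  V <- qr.Q(qr(matrix(rnorm(60 * 2), 60, 2)))
  X <- u1 %*% t(V[, 1]) + u2 %*% t(V[, 2]) + matrix(rnorm(n * 60, sd = 0.01), n, 60)
  pcs <- compute_pcs(X, 2)
  expect_gt(abs(cor(pcs[, 1], u1)), 0.999)
  expect_gt(abs(cor(pcs[, 2], u2)), 0.999)
  expect_equal(unname(apply(pcs, 2, sd)), c(1, 1))
  expect_equal(ncol(compute_pcs(X, 0)), 0)
  expect_error(compute_pcs(X, 200), "between 0 and")
})

test_that("the cis scan finds perfect and planted associations", {
  set.seed(101)
  gm <- random_genotypes(200, 20)
  tss <- list(chrom = "6", tss = 30010000L, strand = "+")
  y <- as.numeric(gm$dosages[, 7])
  names(y) <- gm$samples
  sc <- cis_scan(y, gm, tss)
  expect_equal(sc$best, gm$variants$id[7])
  expect_equal(sc$table$r2[7], 1, tolerance = 1e-12)
  expect_lt(sc$table$p[7], 1e-100)

  # r2 equals the squared Pearson correlation, variant by variant
  y2 <- rnorm(200) + 0.3 * gm$dosages[, 3]
  names(y2) <- gm$samples
  sc2 <- cis_scan(y2, gm, tss)
  r2_oracle <- apply(gm$dosages, 2, function(d) cor(d, y2)^2)
  expect_equal(sc2$table$r2, unname(r2_oracle), tolerance = 1e-12)

  # the window is fully closed: only the variant exactly 1 Mb away stays
  tss_far <- list(chrom = "6", tss = 30020000L + 1e6, strand = "+")
  expect_equal(nrow(cis_scan(y, gm, tss_far)$table), 1)
  expect_equal(cis_scan(y, gm, tss_far)$table$id, gm$variants$id[20])
  expect_error(cis_scan(y, gm, list(chrom = "7", tss = 30010000L)),
               "no variants in the cis window")

  # mean imputation: missing dosages do not derail the scan
  gm$dosages[1:5, 7] <- NA
  sc3 <- cis_scan(y, gm, tss)
  expect_true(is.finite(sc3$table$p[7]))
})

test_that("gene-level permutation p matches the nominal p for one variant", {
  set.seed(111)
  gm <- random_genotypes(150, 1)
  y <- rnorm(150) + 0.25 * gm$dosages[, 1]
  names(y) <- gm$samples
  tss <- list(chrom = "6", tss = 30001000L)
  gp <- gene_permutation_p(y, gm, tss, R = 2000, seed = 5)
  nominal <- cis_scan(y, gm, tss)$table$p[1]
  expect_lt(abs(gp$empirical_p - nominal),
            3 * sqrt(nominal * (1 - nominal) / 2000) + 1e-3)
  expect_error(gene_permutation_p(y, gm, tss, R = 50), "R must be >= 100")
})

test_that("the beta approximation tracks the empirical permutation p", {
  set.seed(121)
  gm <- random_genotypes(120, 40)
  tss <- list(chrom = "6", tss = 30020000L)
  effects <- c(0.12, 0.2, 0.28)
  ratios <- sapply(seq_along(effects), function(i) {
    y <- rnorm(120) + effects[i] * gm$dosages[, 10]
    names(y) <- gm$samples
    gp <- gene_permutation_p(y, gm, tss, R = 1000, seed = 100 + i)
    c(gp$empirical_p, gp$beta_p)
  })
  inside <- ratios[1, ] >= 0.01 & ratios[1, ] <= 0.5
  expect_true(any(inside))
  expect_true(all(abs(ratios[2, inside] / ratios[1, inside] - 1) < 0.30))
})

test_that("BH selection matches the step-up oracle", {
  p <- c(a = 0.001, b = 0.008, c = 0.039, d = 0.041, e = 0.9)
  sel <- fdr_select(p, 0.05)
  expect_setequal(sel$selected, bh_oracle(p, 0.05))
  expect_setequal(sel$selected, c("a", "b"))
  expect_equal(sel$threshold, 0.008)

  tiny <- setNames(rep(1e-10, 100), paste0("g", 1:100))
  expect_length(fdr_select(tiny, 0.05)$selected, 100)

  set.seed(131)
  for (i in 1:20) {
    pr <- setNames(runif(50), paste0("g", 1:50))
    expect_setequal(fdr_select(pr, 0.05)$selected, bh_oracle(pr, 0.05))
  }
  punif1000 <- setNames(runif(1000), paste0("g", 1:1000))
  expect_lte(length(fdr_select(punif1000, 0.05)$selected), 2)
  expect_error(fdr_select(numeric(0)), "empty")
})

test_that("interaction fits satisfy their exact parameterization identities", {
  set.seed(141)
  n <- 200
  g <- rbinom(n, 2, 0.4)
  ids <- sprintf("S%03d", 1:n)
  indiv <- rnorm(n, sd = 1)
  y_u <- indiv + 0.3 * g + rnorm(n, sd = 0.5)
  y_s <- indiv + 0.6 * g + 0.8 + rnorm(n, sd = 0.5)
  ph <- rbind(data.frame(sample_id = ids, condition = "unstim", expr = y_u),
              data.frame(sample_id = ids, condition = "stim", expr = y_s))
  dos <- setNames(g, ids)
  it <- interaction_test(ph, dos)
  expect_equal(it$slope_stim - it$slope_unstim, it$interaction, tolerance = 1e-12)
  expect_equal(it$genotype_main, (it$slope_stim + it$slope_unstim) / 2,
               tolerance = 1e-12)
  expect_gt(it$interaction, 0)
  expect_lt(it$interaction_p, 0.05)

  expect_error(interaction_test(ph, setNames(rep(1, n), ids)),
               "genotype is constant")
  expect_warning(interaction_test(ph[-1, ], dos), "dropped")
})

test_that("interaction test holds its type-I error with no planted effect", {
  set.seed(151)
  rejections <- replicate(400, {
    n <- 55
    g <- rbinom(n, 2, 0.4)
    ids <- sprintf("S%03d", 1:n)
    indiv <- rnorm(n)
    ph <- rbind(
      data.frame(sample_id = ids, condition = "unstim",
                 expr = indiv + 0.3 * g + rnorm(n, sd = 0.6)),
      data.frame(sample_id = ids, condition = "stim",
                 expr = indiv + 0.3 * g + 0.5 + rnorm(n, sd = 0.6)))
    interaction_test(ph, setNames(g, ids))$interaction_p < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("pi1 behaves at the pure-null and pure-alternative extremes", {
  set.seed(161)
  expect_lte(abs(pi1(runif(10000))$pi1), 0.03)
  expect_equal(pi1(rep(1e-7, 100))$pi1, 1)
  expect_error(pi1(runif(10)), "at least 20")
  g <- pi1(runif(1000), grid = TRUE)
  expect_length(g$lambda, 13)
})

test_that("LD r2 matches the D-squared haplotype identity", {
  # founder pool with known two-locus haplotype frequencies; exhaustive
  # ordered pairing makes sample moments equal population moments
  hap <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  counts <- c(10, 4, 3, 8)
  pool <- hap[rep(1:4, counts), ]
  N <- nrow(pool)
  pairs <- expand.grid(h1 = 1:N, h2 = 1:N)
  dos <- pool[pairs$h1, ] + pool[pairs$h2, ]
  v <- data.frame(chrom = "6", pos = c(100L, 200L), ref = "A", alt = "G")
  gm <- genotype_matrix(sprintf("S%05d", seq_len(N^2)), v, dos)
  freq <- setNames(counts / N, c("00", "01", "10", "11"))
  expect_equal(ld_r2(gm, gm$variants$id[1], gm$variants$id[2]),
               ld_oracle(freq, 1, 2), tolerance = 1e-12)

  set.seed(171)
  big <- random_genotypes(10000, 2)
  expect_lte(ld_r2(big, big$variants$id[1], big$variants$id[2]), 0.01)
  mono <- big
  mono$dosages[, 1] <- 2
  expect_error(ld_r2(mono, mono$variants$id[1], mono$variants$id[2]),
               "monomorphic")
})

test_that("covariate count selection rewards removing a planted confounder", {
  set.seed(181)
  n <- 120
  gm <- random_genotypes(n, 15)
  conf <- rnorm(n, sd = 3)          # strong shared confounder -> PC1
  tssdf <- data.frame(gene = paste0("G", 1:6), chrom = "6",
                      tss = 30005000L + (1:6) * 100L, strand = "+",
                      stringsAsFactors = FALSE)
  pheno <- t(sapply(1:6, function(i)
    conf + 0.45 * gm$dosages[, i] + rnorm(n, sd = 1)))
  rownames(pheno) <- tssdf$gene
  colnames(pheno) <- gm$samples
  res <- choose_covariate_count(pheno, gm, tssdf, ks = c(0, 1), R = 150,
                                seed = 7)
  expect_equal(res$k, 1)
  expect_gt(res$counts["1"], res$counts["0"])

  single <- choose_covariate_count(pheno, gm, tssdf, ks = 1, R = 150, seed = 7)
  expect_equal(single$k, 1)

  noise <- matrix(rnorm(6 * n), 6, n,
                  dimnames = list(tssdf$gene, gm$samples))
  null_res <- choose_covariate_count(noise, gm, tssdf, ks = c(0, 1, 2),
                                     R = 150, seed = 8)
  expect_equal(null_res$k, 0)  # ties resolve to the smallest k
})
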