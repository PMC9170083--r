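# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A minimal hand-built expression table: `alleles` is a list per sample
# of named locus -> c(allele1, allele2); tpm values supplied in order.
make_expr <- function(samples, locus, alleles, tpm, condition = "unstim") {
  stopifnot(length(tpm) == 2 * length(samples))
  data.frame(
    sample_id = rep(samples, each = 2),
    locus = locus,
    allele = as.vector(t(alleles)),
    copy = rep(1:2, length(samples)),
    condition = condition,
    tpm = tpm,
    stringsAsFactors = FALSE)
}

# Single-locus equifrequent cohort used throughout: the coordinated
# study-shaped configuration (63 individuals, 15 alleles).
one_locus_config <- function(seed, n = 63, n_alleles = 15, sigma_A = 0.10,
                             sigma_G = 0.40, sigma_E = 0.08, locus = "B",
                             mu = log(1870), mode = "shared", ...) {
  pool <- stats::setNames(rep(1 / n_alleles, n_alleles),
                          sprintf("%s*%02d:01", locus, seq_len(n_alleles)))
  generator_config(
    n_individuals = n, loci = locus,
    allele_pool = stats::setNames(list(pool), locus),
    mu_locus = stats::setNames(mu, locus),
    sigma_A = sigma_A, sigma_G = sigma_G, sigma_E = sigma_E,
    allele_effect_mode = mode, seed = seed, ...)
}

# Large sample of heterozygous ASE values with fresh per-copy allele
# effects (so the effect differences are i.i.d. normal).
het_ase_draws <- function(n, sigma_A, sigma_E, seed, sigma_G = 0.3) {
  cfg <- one_locus_config(seed, n = ceiling(n * 1.05) + 50, n_alleles = 60,
                          sigma_A = sigma_A, sigma_G = sigma_G,
                          sigma_E = sigma_E, mode = "fresh")
  expr <- simulate_expression(sample_cohort(cfg), "unstim")
  a <- ase_table(expr)$ase
  if (length(a) < n) stop("not enough heterozygous draws")
  a[seq_len(n)]
}

# Genotype matrix of independent binomial variants (no LD).
random_genotypes <- function(n, m, maf = NULL, chrom = "6", start = 30e6,
                             step = 1000) {
  if (is.null(maf)) maf <- stats::runif(m, 0.1, 0.5)
  dos <- sapply(seq_len(m), function(j) stats::rbinom(n, 2, maf[j]))
  variants <- data.frame(chrom = chrom, pos = start + step * seq_len(m),
                         ref = "A", alt = "G", stringsAsFactors = FALSE)
  genotype_matrix(sprintf("S%04d", seq_len(n)), variants, dos)
}

# Two-locus haplotype reference table plus a haplotype-structured
# generator configuration for assignment / contrast tests.
haplo_demo_config <- function(seed, n = 60, sigma_H = 0.3, sigma_A = 0.15,
                              sigma_G = 0.25, sigma_E = 0.08, n_hap = 8) {
  loci <- c("A", "B", "C")
  ht <- data.frame(
    A = sprintf("A*%02d:01", seq_len(n_hap)),
    B = sprintf("B*%02d:01", seq_len(n_hap)),
    C = sprintf("C*%02d:01", seq_len(n_hap)),
    freq = c(0.35, rep(0.65 / (n_hap - 1), n_hap - 1)),
    label = sprintf("H%02d", seq_len(n_hap)),
    stringsAsFactors = FALSE)
  pools <- lapply(loci, function(l) {
    a <- unique(ht[[l]])
    stats::setNames(rep(1 / length(a), length(a)), a)
  })
  names(pools) <- loci
  generator_config(
    n_individuals = n, loci = loci, allele_pool = pools,
    haplotype_table = ht,
    mu_locus = stats::setNames(log(c(900, 1900, 1200)), loci),
    sigma_A = sigma_A, sigma_G = sigma_G, sigma_H = sigma_H,
    sigma_E = sigma_E, seed = seed)
}
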