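# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms (enumeration, normal
# equations, rank-then-Pearson) than the code paths they verify.

# Exact Hardy-Weinberg test by full enumeration of heterozygote counts
# conditional on allele counts (probabilities summed over outcomes at
# most as likely as the observed one).
hwe_exact_oracle <- function(n_rr, n_ra, n_aa) {
  n <- n_rr + n_ra + n_aa
  n_alt <- 2 * n_aa + n_ra
  rare <- min(n_alt, 2 * n - n_alt)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    homr <- (rare - h) / 2
    homc <- n - h - homr
    lgamma(n + 1) - lgamma(h + 1) - lgamma(homr + 1) - lgamma(homc + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_ra, hets)]
  sum(pr[pr <= obs + 1e-12])
}

# Simple-regression coefficients via the normal equations.
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  list(intercept = beta[1], slope = beta[2],
       residual_se = sqrt(sum(res^2) / (length(y) - 2)))
}

# Spearman rho as Pearson correlation of ranks.
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Benjamini-Hochberg selection by direct step-up enumeration.
bh_oracle <- function(p, level) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= level * seq_len(m) / m)
  if (!length(below)) return(character(0))
  k <- max(below)
  names(p)[ord[seq_len(k)]]
}

# Population LD r^2 from founder haplotype frequencies: D^2/(p1 q1 p2 q2).
ld_oracle <- function(hap_freq, a1, a2) {
  # hap_freq: named numeric over two-locus haplotypes "00","01","10","11"
  p1 <- hap_freq["10"] + hap_freq["11"]
  p2 <- hap_freq["01"] + hap_freq["11"]
  D <- hap_freq["11"] - p1 * p2
  unname(D^2 / (p1 * (1 - p1) * p2 * (1 - p2)))
}

# closed-form median ASE when only allele effects and residuals act
ase_median_closed_form <- function(sigma_a, sigma_e) {
  1 / (1 + exp(stats::qnorm(0.75) * sqrt(2 * (sigma_a^2 + sigma_e^2))))
}
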