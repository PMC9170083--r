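#' Allele-specific expression (ASE) of an allele pair
#'
#' The ASE statistic is the tpm of the lower-expressed allele divided by
#' the total tpm of both alleles at the locus in one individual. It lies
#' in (0, 0.5], with 0.5 meaning perfectly balanced biallelic
#' expression.
#'
#' @param tpm1,tpm2 Positive tpm values of the two allele copies
#'   (vectorized).
#' @return `pmin(tpm1, tpm2) / (tpm1 + tpm2)`.
#' @export
compute_ase <- function(tpm1, tpm2) {
  if (any(!is.finite(tpm1) | tpm1 <= 0) || any(!is.finite(tpm2) | tpm2 <= 0))
    stop("tpm values must be positive")
  pmin(tpm1, tpm2) / (tpm1 + tpm2)
}

# row indices of the two allele records per (sample, locus, condition),
# in a fixed key order
.pair_index <- function(expr) {
  key <- paste(expr$sample_id, expr$locus, expr$condition, sep = "\r")
  ord <- order(key, expr$copy)
  n2 <- length(ord)
  if (n2 %% 2L != 0L || any(key[ord[seq(1, n2, 2)]] != key[ord[seq(2, n2, 2)]]))
    stop("expression table does not hold exactly 2 records per (sample, locus, condition)")
  i1 <- ord[seq(1, n2, 2)]
  i2 <- ord[seq(2, n2, 2)]
  data.frame(sample_id = expr$sample_id[i1], locus = expr$locus[i1],
             condition = expr$condition[i1], i1 = i1, i2 = i2,
             het = expr$allele[i1] != expr$allele[i2],
             stringsAsFactors = FALSE)
}

#' Per-individual ASE table
#'
#' Computes one ASE record per (sample, locus, condition). Homozygous
#' individuals are excluded by default: their two records carry the same
#' allele name, so the ratio conflates copies rather than alleles.
#'
#' @param expr Validated expression data frame.
#' @param include_homozygotes Include homozygotes as min-copy / total?
#' @return Data frame with `sample_id`, `locus`, `condition`, `ase`.
#' @export
ase_table <- function(expr, include_homozygotes = FALSE) {
  px <- .pair_index(expr)
  if (!include_homozygotes) px <- px[px$het, , drop = FALSE]
  data.frame(sample_id = px$sample_id, locus = px$locus,
             condition = px$condition,
             ase = compute_ase(expr$tpm[px$i1], expr$tpm[px$i2]),
             stringsAsFactors = FALSE)
}

#' Allele-constrained permutation of expression values
#'
#' For every allele name, shuffles the observed tpm values uniformly at
#' random among all carrier slots of that allele, for the whole cohort
#' simultaneously; each individual's allele names are unchanged. This is
#' the null in which allele-level expression is preserved but
#' within-individual coordination is broken. Permutations are drawn per
#' allele name in lexicographic order from the current RNG stream.
#'
#' @param expr Expression data frame restricted to a single condition.
#' @return `expr` with permuted `tpm`.
#' @export
permute_within_alleles <- function(expr) {
  if (length(unique(expr$condition)) > 1)
    stop("permute_within_alleles expects a single condition")
  groups <- split(seq_len(nrow(expr)), paste(expr$locus, expr$allele, sep = "\r"))
  tpm <- expr$tpm
  for (idx in groups) {
    k <- length(idx)
    if (k > 1L) tpm[idx] <- tpm[idx][sample.int(k)]
  }
  expr$tpm <- tpm
  expr
}

#' Permutation test of median expression balance
#'
#' Tests, per locus, whether the observed median ASE is closer to the
#' maximum possible balance (0.5) than expected when tpm values are
#' shuffled among carriers of each allele ([permute_within_alleles()]).
#' For each of `R` replicates the per-locus median ASE is recomputed;
#' the one-sided empirical p-value is `(b + 1) / (R + 1)` where `b`
#' counts replicate medians greater than or equal to the observed
#' median (ties count against rejection).
#'
#' @param expr Expression data frame, single condition.
#' @param R Number of permutation replicates (>= 1).
#' @param include_homozygotes Passed to [ase_table()].
#' @param seed Optional integer seed for the permutation stream.
#' @return An object of class `ase_perm_test`: a per-locus table with
#'   observed medians and empirical p-values, plus the `R x loci` matrix
#'   of replicate medians.
#' @export
permutation_test_median_ase <- function(expr, R = 1000, include_homozygotes = FALSE,
                                        seed = NULL) {
  if (R < 1) stop("R must be >= 1")
  if (length(unique(expr$condition)) > 1)
    stop("permutation test expects a single condition")
  if (!is.null(seed)) set.seed(seed)

  px <- .pair_index(expr)
  if (!include_homozygotes) px <- px[px$het, , drop = FALSE]
  loci <- sort(unique(expr$locus))
  n_inf <- table(factor(px$locus, levels = loci))
  if (any(n_inf < 2))
    stop("fewer than 2 informative individuals at locus: ",
         paste(loci[n_inf < 2], collapse = ", "))

  tpm <- expr$tpm
  locus_f <- factor(px$locus, levels = loci)
  med_by_locus <- function(v) {
    a <- pmin(v[px$i1], v[px$i2]) / (v[px$i1] + v[px$i2])
    tapply(a, locus_f, stats::median)
  }
  observed <- med_by_locus(tpm)

  groups <- split(seq_len(nrow(expr)), paste(expr$locus, expr$allele, sep = "\r"))
  groups <- groups[lengths(groups) > 1L]
  reps <- matrix(NA_real_, R, length(loci), dimnames = list(NULL, loci))
  perm <- tpm
  for (r in seq_len(R)) {
    perm[] <- tpm
    for (idx in groups) perm[idx] <- perm[idx][sample.int(length(idx))]
    reps[r, ] <- med_by_locus(perm)
  }

  b <- colSums(reps >= rep(observed, each = R))
  table <- data.frame(
    locus = loci,
    n = as.integer(n_inf),
    observed_median_ase = as.numeric(observed),
    null_median = apply(reps, 2, stats::median),
    empirical_p = (b + 1) / (R + 1),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = table, replicate_medians = reps, R = R,
                 condition = unique(expr$condition),
                 include_homozygotes = include_homozygotes),
            class = "ase_perm_test")
}

#' @export
print.ase_perm_test <- function(x, ...) {
  cat(sprintf("Allele-constrained permutation test of median ASE (R = %d, condition: %s)\n",
              x$R, x$condition))
  tab <- x$table
  tab$empirical_p <- format.pval(tab$empirical_p, digits = 3)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.ase_perm_test <- function(object, ...) {
  cat(sprintf("Permutation replicates: %d; loci: %s\n", object$R,
              paste(object$table$locus, collapse = ", ")))
  cat("Replicate median ASE quantiles per locus:\n")
  print(apply(object$replicate_medians, 2, stats::quantile,
              probs = c(0.025, 0.5, 0.975)), digits = 4)
  invisible(object)
}

#' Paired test of ASE between conditions
#'
#' Wilcoxon signed-rank test on paired per-individual ASE differences at
#' one locus (zero differences dropped, Wilcoxon's original treatment).
#' Individuals present in only one condition are dropped with a warning.
#'
#' @param ase_a,ase_b ASE tables from [ase_table()] for the two
#'   conditions.
#' @param locus Locus to test.
#' @return List with the signed-rank statistic, two-sided p-value,
#'   per-condition medians, number of pairs and number dropped.
#' @export
paired_condition_test <- function(ase_a, ase_b, locus) {
  a <- ase_a[ase_a$locus == locus, ]
  b <- ase_b[ase_b$locus == locus, ]
  m <- merge(a[c("sample_id", "ase")], b[c("sample_id", "ase")],
             by = "sample_id", suffixes = c("_a", "_b"))
  dropped <- nrow(a) + nrow(b) - 2L * nrow(m)
  if (dropped > 0)
    warning(sprintf("%d unpaired ASE records dropped at locus %s", dropped, locus))
  if (nrow(m) < 1) stop("no paired samples at locus ", locus)
  d <- m$ase_b - m$ase_a
  if (all(d == 0)) {
    res <- list(statistic = 0, p.value = 1)
  } else {
    wt <- stats::wilcox.test(m$ase_b, m$ase_a, paired = TRUE, exact = FALSE)
    res <- list(statistic = unname(wt$statistic), p.value = wt$p.value)
  }
  list(locus = locus, statistic = res$statistic, p.value = res$p.value,
       median_a = stats::median(m$ase_a), median_b = stats::median(m$ase_b),
       n_pairs = nrow(m), n_dropped = dropped)
}

#' Spearman correlation between paired allele expression values
#'
#' For heterozygous individuals at a locus, correlates the
#' lower-expressed against the higher-expressed allele tpm across
#' individuals (rank correlation, asymptotic t-approximation p-value).
#' The lower/higher ordering is deterministic.
#'
#' @param expr Expression data frame.
#' @param locus Locus name.
#' @param condition Condition to use.
#' @return List with `rho`, `p.value` and `n` pairs.
#' @export
spearman_allele_pairs <- function(expr, locus, condition) {
  e <- expr[expr$locus == locus & expr$condition == condition, ]
  px <- .pair_index(e)
  px <- px[px$het, , drop = FALSE]
  if (nrow(px) < 3) stop("fewer than 3 heterozygous individuals")
  lo <- pmin(e$tpm[px$i1], e$tpm[px$i2])
  hi <- pmax(e$tpm[px$i1], e$tpm[px$i2])
  ct <- stats::cor.test(lo, hi, method = "spearman", exact = FALSE)
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = nrow(px))
}
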