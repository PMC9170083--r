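#' Assign reference haplotypes to typed individuals
#'
#' Greedy decomposition of unphased HLA genotypes against a table of
#' reference (common) haplotypes. If exactly one reference haplotype is
#' compatible with an individual's genotype, it is assigned and the
#' complementary haplotype is derived from the remaining alleles. If two
#' reference haplotypes jointly compose the genotype exactly (and do so
#' uniquely), both are assigned. Individuals compatible with no
#' reference haplotype, or ambiguously with several, are marked
#' unresolved.
#'
#' @param typings Data frame with `sample_id` and `<locus>_1`,
#'   `<locus>_2` allele-name columns for every reference locus (see
#'   [cohort_typings()]).
#' @param reference Data frame of reference haplotypes: one column per
#'   locus plus `freq`, optionally `label` (defaults to `H1`, `H2`, ...).
#'   Rows are considered in decreasing frequency order.
#' @return Object of class `haplotype_assignment`: the per-sample
#'   assignment table (labels of carried reference haplotypes, resolved
#'   flag, and the inferred second-haplotype allele per locus) plus the
#'   reference table.
#' @export
assign_haplotypes <- function(typings, reference) {
  loci <- setdiff(names(reference), c("freq", "label"))
  need <- c("sample_id", paste0(rep(loci, each = 2), c("_1", "_2")))
  missing_cols <- setdiff(need, names(typings))
  if (length(missing_cols))
    stop("typings missing columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(reference$label)) reference$label <- paste0("H", seq_len(nrow(reference)))
  reference <- reference[order(-reference$freq), , drop = FALSE]
  rownames(reference) <- NULL

  n <- nrow(typings)
  hap1 <- hap2 <- rep(NA_character_, n)
  resolved <- rep(FALSE, n)
  second <- matrix(NA_character_, n, length(loci), dimnames = list(NULL, loci))

  geno <- lapply(loci, function(loc)
    cbind(typings[[paste0(loc, "_1")]], typings[[paste0(loc, "_2")]]))
  names(geno) <- loci

  ref_alleles <- as.matrix(reference[loci])

  for (i in seq_len(n)) {
    g <- lapply(loci, function(loc) geno[[loc]][i, ])
    names(g) <- loci
    compat <- vapply(seq_len(nrow(reference)), function(r)
      all(vapply(loci, function(loc) ref_alleles[r, loc] %in% g[[loc]], logical(1))),
      logical(1))
    cset <- which(compat)
    if (length(cset) == 1L) {
      r <- cset
      hap1[i] <- reference$label[r]
      comp <- vapply(loci, function(loc) {
        pair <- g[[loc]]
        if (pair[1] == ref_alleles[r, loc]) pair[2] else pair[1]
      }, character(1))
      second[i, ] <- comp
      hap2[i] <- if (all(comp == ref_alleles[r, loci])) reference$label[r] else NA_character_
      resolved[i] <- TRUE
    } else if (length(cset) >= 2L) {
      # a pair of reference haplotypes may explain the genotype exactly
      pairs <- utils::combn(cset, 2)
      composes <- apply(pairs, 2, function(pr)
        all(vapply(loci, function(loc)
          identical(sort(unname(c(ref_alleles[pr[1], loc], ref_alleles[pr[2], loc]))),
                    sort(unname(g[[loc]]))), logical(1))))
      if (sum(composes) == 1L) {
        pr <- pairs[, which(composes)]
        hap1[i] <- reference$label[pr[1]]
        hap2[i] <- reference$label[pr[2]]
        second[i, ] <- ref_alleles[pr[2], loci]
        resolved[i] <- TRUE
      }
    }
  }

  assignment <- data.frame(sample_id = typings$sample_id, hap1 = hap1,
                           hap2 = hap2, resolved = resolved,
                           stringsAsFactors = FALSE)
  for (loc in loci) assignment[[paste0("second_", loc)]] <- second[, loc]
  structure(list(assignment = assignment, reference = reference, loci = loci),
            class = "haplotype_assignment")
}

#' @export
print.haplotype_assignment <- function(x, ...) {
  cat(sprintf("Haplotype assignment: %d samples, %d reference haplotypes (%s)\n",
              nrow(x$assignment), nrow(x$reference),
              paste(x$loci, collapse = "~")))
  cat(sprintf("  resolved: %d (%.1f%%)\n", sum(x$assignment$resolved),
              100 * mean(x$assignment$resolved)))
  invisible(x)
}

# tpm of the allele attributed to a haplotype, per sample and locus.
# which = "carried": alleles of the named reference haplotype;
# which = "second": the inferred complementary alleles.
# Loci where the individual is homozygous are skipped (ambiguous
# attribution), as are loci without expression records.
.hap_tpm <- function(expr, assignment, label, which = c("carried", "second"),
                     condition = NULL) {
  which <- match.arg(which)
  asg <- assignment$assignment
  ref <- assignment$reference
  if (!label %in% ref$label) stop("unknown haplotype label: ", label)
  if (!is.null(condition)) expr <- expr[expr$condition == condition, ]
  if (length(unique(expr$condition)) > 1)
    stop("expression spans several conditions; pass `condition`")
  carriers <- asg[asg$resolved & (asg$hap1 == label |
                                  (!is.na(asg$hap2) & asg$hap2 == label)), ]
  loci <- intersect(assignment$loci, unique(expr$locus))
  out <- data.frame(sample_id = carriers$sample_id, stringsAsFactors = FALSE)
  for (loc in loci) {
    want <- if (which == "carried")
      rep(ref[[loc]][ref$label == label], nrow(carriers))
    else carriers[[paste0("second_", loc)]]
    out[[loc]] <- vapply(seq_len(nrow(carriers)), function(i) {
      e <- expr[expr$sample_id == carriers$sample_id[i] & expr$locus == loc, ]
      if (nrow(e) != 2) return(NA_real_)
      if (e$allele[1] == e$allele[2]) return(NA_real_)  # homozygous: ambiguous
      hit <- which(e$allele == want[i])
      if (length(hit) != 1) return(NA_real_)
      e$tpm[hit]
    }, numeric(1))
  }
  out
}

#' Inter-locus expression regression within a haplotype
#'
#' Ordinary least squares of the second locus' allele tpm on the first
#' locus' allele tpm, restricted to the alleles carried on the named
#' reference haplotype. Individuals homozygous at either locus are
#' skipped (attribution by allele name is ambiguous).
#'
#' @param expr Expression data frame (single condition, or pass
#'   `condition`).
#' @param assignment A [assign_haplotypes()] result.
#' @param haplotype_label Reference haplotype label.
#' @param locus_pair Character vector of two loci `(x, y)`.
#' @param condition Optional condition filter.
#' @return List of class `interlocus_fit`: `slope`, `intercept`,
#'   `residual_se` (`sqrt(RSS / (n - 2))`), `n`, `n_skipped`.
#' @export
interlocus_regression <- function(expr, assignment, haplotype_label, locus_pair,
                                  condition = NULL) {
  stopifnot(length(locus_pair) == 2)
  ht <- .hap_tpm(expr, assignment, haplotype_label, "carried", condition)
  x <- ht[[locus_pair[1]]]; y <- ht[[locus_pair[2]]]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3)
    stop(sprintf("fewer than 3 usable carriers of %s for loci %s~%s",
                 haplotype_label, locus_pair[1], locus_pair[2]))
  fit <- stats::lm(y[ok] ~ x[ok])
  rss <- sum(stats::residuals(fit)^2)
  structure(list(haplotype = haplotype_label, locus_x = locus_pair[1],
                 locus_y = locus_pair[2],
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residual_se = sqrt(rss / (sum(ok) - 2)),
                 n = sum(ok), n_skipped = sum(!ok)),
            class = "interlocus_fit")
}

#' @export
print.interlocus_fit <- function(x, ...) {
  cat(sprintf("Inter-locus fit on %s: %s ~ %s\n", x$haplotype, x$locus_y, x$locus_x))
  cat(sprintf("  slope %.4g, intercept %.4g, residual SE %.4g, n = %d (%d skipped)\n",
              x$slope, x$intercept, x$residual_se, x$n, x$n_skipped))
  invisible(x)
}

#' Regression tightness: shared versus second haplotype
#'
#' For individuals carrying exactly one copy of a common reference
#' haplotype, compares the residual standard error of the inter-locus
#' expression regression computed on the shared (common) haplotype's
#' alleles against the same regression computed on the individuals'
#' second haplotypes — on the same individuals. A shared haplotype
#' effect tightens the common-haplotype fit.
#'
#' @param expr Expression data frame (single condition, or pass
#'   `condition`).
#' @param assignment A [assign_haplotypes()] result.
#' @param common_haplotype Label of the common haplotype.
#' @param condition Optional condition filter.
#' @return Data frame with one row per locus pair: `se_common`,
#'   `se_second`, `n`.
#' @export
shared_vs_second_contrast <- function(expr, assignment, common_haplotype,
                                      condition = NULL) {
  asg <- assignment$assignment
  one_copy <- asg$resolved & xor(asg$hap1 == common_haplotype,
                                 !is.na(asg$hap2) & asg$hap2 == common_haplotype)
  sub <- assignment
  sub$assignment <- asg[one_copy, , drop = FALSE]
  # orient so the common haplotype is hap1 for attribution
  swap <- !is.na(sub$assignment$hap2) & sub$assignment$hap2 == common_haplotype
  if (any(swap)) {
    h1 <- sub$assignment$hap1[swap]
    sub$assignment$hap1[swap] <- common_haplotype
    sub$assignment$hap2[swap] <- h1
    ref <- sub$reference
    for (loc in sub$loci)
      sub$assignment[[paste0("second_", loc)]][swap] <-
        ref[[loc]][match(h1, ref$label)]
  }
  com <- .hap_tpm(expr, sub, common_haplotype, "carried", condition)
  sec <- .hap_tpm(expr, sub, common_haplotype, "second", condition)
  loci <- setdiff(names(com), "sample_id")
  pairs <- utils::combn(loci, 2)
  res_se <- function(x, y) {
    fit <- stats::lm(y ~ x)
    sqrt(sum(stats::residuals(fit)^2) / (length(x) - 2))
  }
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    lx <- pairs[1, k]; ly <- pairs[2, k]
    ok <- is.finite(com[[lx]]) & is.finite(com[[ly]]) &
      is.finite(sec[[lx]]) & is.finite(sec[[ly]])
    if (sum(ok) < 3)
      stop(sprintf("fewer than 3 usable carriers for loci %s~%s", lx, ly))
    data.frame(haplotype = common_haplotype, locus_x = lx, locus_y = ly,
               se_common = res_se(com[[lx]][ok], com[[ly]][ok]),
               se_second = res_se(sec[[lx]][ok], sec[[ly]][ok]),
               n = sum(ok), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
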