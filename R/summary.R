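#' Per-locus expression summary
#'
#' Arithmetic mean and sample SD of tpm over all allele records at each
#' locus in one condition.
#'
#' @param expr Expression data frame.
#' @param condition Condition to summarize.
#' @return Data frame with `locus`, `mean_tpm`, `sd_tpm`, `n`.
#' @export
locus_summary <- function(expr, condition) {
  e <- expr[expr$condition == condition, ]
  if (nrow(e) == 0) stop("no records for condition ", condition)
  loci <- sort(unique(e$locus))
  out <- do.call(rbind, lapply(loci, function(loc) {
    v <- e$tpm[e$locus == loc]
    data.frame(locus = loc, mean_tpm = mean(v),
               sd_tpm = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Maximum fold variation between alleles of a locus
#'
#' Computes a central tpm value per allele (mean or median across all
#' carrier records) and reports the ratio of the highest to the lowest
#' allele, with the alleles achieving it. Alleles carried by a single
#' individual are flagged low-support.
#'
#' @param expr Expression data frame.
#' @param condition Condition to use.
#' @param statistic `"mean"` or `"median"` per-allele central value.
#' @return Data frame with `locus`, `statistic`, `max_ratio`,
#'   `top_allele`, `bottom_allele`, `n_alleles`,
#'   `low_support_alleles` (comma-separated single-carrier alleles).
#' @export
fold_variation <- function(expr, condition, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  fun <- if (statistic == "mean") mean else stats::median
  e <- expr[expr$condition == condition, ]
  if (nrow(e) == 0) stop("no records for condition ", condition)
  loci <- sort(unique(e$locus))
  out <- do.call(rbind, lapply(loci, function(loc) {
    el <- e[e$locus == loc, ]
    vals <- tapply(el$tpm, el$allele, fun)
    carriers <- tapply(el$sample_id, el$allele, function(s) length(unique(s)))
    if (length(vals) < 2)
      stop("fewer than 2 allele names at locus ", loc)
    top <- names(vals)[which.max(vals)]
    bottom <- names(vals)[which.min(vals)]
    low <- names(carriers)[carriers == 1]
    data.frame(locus = loc, statistic = statistic,
               max_ratio = unname(max(vals) / min(vals)),
               top_allele = top, bottom_allele = bottom,
               n_alleles = length(vals),
               low_support_alleles = paste(low, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Fold upregulation between paired conditions
#'
#' Pairs records by (sample, locus, allele, copy) and computes the
#' per-record tpm fold `stim / unstim`. Reports the mean (and median)
#' fold per allele, the per-locus mean of per-record folds, and the
#' per-locus Spearman correlation between paired stimulated and
#' unstimulated tpm values. Mean fold is the mean of per-record ratios,
#' not the ratio of means.
#'
#' @param expr_unstim,expr_stim Expression data frames for the two
#'   conditions.
#' @return List of class `fold_upregulation` with elements `per_allele`,
#'   `per_locus` and `n_dropped` (unpaired records).
#' @export
fold_upregulation <- function(expr_unstim, expr_stim) {
  key <- c("sample_id", "locus", "allele", "copy")
  m <- merge(expr_unstim[c(key, "tpm")], expr_stim[c(key, "tpm")],
             by = key, suffixes = c("_unstim", "_stim"))
  n_dropped <- nrow(expr_unstim) + nrow(expr_stim) - 2L * nrow(m)
  if (n_dropped > 0)
    warning(sprintf("%d unpaired expression records dropped", n_dropped))
  if (nrow(m) == 0) stop("no paired records between conditions")
  m$fold <- m$tpm_stim / m$tpm_unstim

  per_allele <- do.call(rbind, lapply(split(m, paste(m$locus, m$allele, sep = "\r")),
    function(g) data.frame(locus = g$locus[1], allele = g$allele[1],
                           mean_fold = mean(g$fold),
                           median_fold = stats::median(g$fold),
                           n = nrow(g), stringsAsFactors = FALSE)))
  per_allele <- per_allele[order(per_allele$locus, per_allele$allele), ]
  rownames(per_allele) <- NULL

  per_locus <- do.call(rbind, lapply(split(m, m$locus), function(g) {
    ct <- suppressWarnings(stats::cor.test(g$tpm_unstim, g$tpm_stim,
                                           method = "spearman", exact = FALSE))
    data.frame(locus = g$locus[1], mean_fold = mean(g$fold),
               median_fold = stats::median(g$fold),
               spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
               n = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(per_locus) <- NULL

  structure(list(per_allele = per_allele, per_locus = per_locus,
                 n_dropped = n_dropped),
            class = "fold_upregulation")
}

#' @export
print.fold_upregulation <- function(x, ...) {
  cat("Stimulation fold upregulation (per-record stim/unstim ratios)\n")
  print(x$per_locus, row.names = FALSE, digits = 3)
  if (x$n_dropped > 0)
    cat(sprintf("  (%d unpaired records dropped)\n", x$n_dropped))
  invisible(x)
}
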