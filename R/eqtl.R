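#' Variant QC thresholds
#'
#' Defaults follow common array-genotyping practice: minor allele
#' frequency at least 1%, genotype missingness at most 2.5%, and
#' Hardy-Weinberg equilibrium p-value at least 1e-5.
#'
#' @param maf_min Minimum minor allele frequency.
#' @param missing_max Maximum genotype missingness.
#' @param hwe_p_min Minimum HWE p-value.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min = 0.01, missing_max = 0.025, hwe_p_min = 1e-5) {
  for (v in c(maf_min, missing_max, hwe_p_min))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("thresholds must be single numbers in [0, 1]")
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 hwe_p_min = hwe_p_min), class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' 1-df chi-square goodness-of-fit of observed genotype counts against
#' the expected Hardy-Weinberg frequencies computed from the sample
#' allele counts. Monomorphic variants return p = 1.
#'
#' @param n_rr,n_ra,n_aa Counts of reference homozygotes, heterozygotes
#'   and alternate homozygotes.
#' @return Two-sided p-value.
#' @export
hwe_test <- function(n_rr, n_ra, n_aa) {
  if (any(c(n_rr, n_ra, n_aa) < 0)) stop("counts must be non-negative")
  n <- n_rr + n_ra + n_aa
  if (n < 1) stop("total count must be >= 1")
  p <- (2 * n_rr + n_ra) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  expected <- n * c(p^2, 2 * p * q, q^2)
  chi2 <- sum((c(n_rr, n_ra, n_aa) - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# per-variant QC metrics on a dosage matrix
.variant_qc_metrics <- function(dosages) {
  n <- nrow(dosages)
  miss <- colMeans(is.na(dosages))
  af <- colMeans(dosages, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(dosages)), function(j) {
    d <- dosages[, j]
    d <- d[!is.na(d)]
    hwe_test(sum(d == 0), sum(d == 1), sum(d == 2))
  }, numeric(1))
  data.frame(id = colnames(dosages), maf = maf, missingness = miss,
             hwe_p = hwe_p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter variants by MAF, missingness and HWE
#'
#' Tests are applied in a fixed, logged order: minor allele frequency
#' (computed on non-missing calls), then missingness, then HWE; the
#' first failing rule is recorded as the variant's fate. Filtering is
#' idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()].
#' @return List with `genotypes` (the filtered matrix) and `log` (a
#'   per-variant data frame of metrics and fate: `"pass"`, `"maf"`,
#'   `"missing"` or `"hwe"`).
#' @export
qc_filter_variants <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(thresholds, "qc_thresholds"))
  m <- .variant_qc_metrics(gm$dosages)
  fate <- rep("pass", nrow(m))
  fate[m$hwe_p < thresholds$hwe_p_min] <- "hwe"
  fate[m$missingness > thresholds$missing_max] <- "missing"
  fate[m$maf < thresholds$maf_min] <- "maf"
  m$fate <- fate
  keep <- fate == "pass"
  filtered <- genotype_matrix(gm$samples, gm$variants[keep, , drop = FALSE],
                              gm$dosages[, keep, drop = FALSE])
  list(genotypes = filtered, log = m)
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard normal quantiles through their ranks (ties
#' receive the average rank): `qnorm((rank - 0.5) / n)`.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Transformed vector.
#' @export
inverse_normal_transform <- function(values) {
  if (anyNA(values)) stop("values must not contain NA")
  if (length(unique(values)) < 2) stop("need at least 2 distinct values")
  stats::qnorm((rank(values, ties.method = "average") - 0.5) / length(values))
}

#' Residualize a phenotype on covariates
#'
#' OLS residuals of the phenotype on the covariates plus an intercept.
#'
#' @param phenotype Numeric vector.
#' @param covariates Numeric matrix (or `NULL` for intercept only).
#' @return Residual vector.
#' @export
residualize <- function(phenotype, covariates = NULL) {
  x <- cbind(intercept = rep(1, length(phenotype)), covariates)
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x))
    stop("covariate matrix is rank deficient after adding an intercept")
  as.numeric(stats::resid(stats::lm.fit(x, phenotype)))
}

#' Principal component covariates
#'
#' Scores of the top-k principal components of the column-centered data
#' matrix, each score vector centered and scaled to unit SD.
#'
#' @param x Samples-by-features numeric matrix.
#' @param k Number of components (0 gives an empty covariate set).
#' @return `nrow(x)` by `k` matrix of standardized scores.
#' @export
compute_pcs <- function(x, k) {
  x <- as.matrix(x)
  if (k < 0 || k > min(dim(x))) stop("k must be between 0 and min(dim(x))")
  if (k == 0) return(matrix(numeric(0), nrow(x), 0))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  scale(scores)
}

# mean-impute missing dosages per variant (scan-time only)
.impute_dosages <- function(dosages) {
  nas <- which(is.na(dosages), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(dosages, na.rm = TRUE)
    dosages[nas] <- mu[nas[, 2]]
  }
  dosages
}

# fast per-variant simple regressions of y on each column of X
.scan_stats <- function(X, y) {
  n <- length(y)
  yc <- y - mean(y)
  xc <- sweep(X, 2, colMeans(X))
  sxx <- colSums(xc^2)
  syy <- sum(yc^2)
  sxy <- as.numeric(crossprod(xc, yc))
  ok <- sxx > 0 & syy > 0
  slope <- ifelse(ok, sxy / sxx, NA_real_)
  r2 <- ifelse(ok, sxy^2 / (sxx * syy), NA_real_)
  r2 <- pmin(r2, 1)
  tt <- sqrt(pmax(n - 2, 0)) * sqrt(r2) / sqrt(pmax(1 - r2, .Machine$double.eps))
  p <- ifelse(ok, 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE), NA_real_)
  list(slope = slope, r2 = r2, p = p)
}

#' Cis scan: per-variant association with a phenotype
#'
#' Simple linear regression of the (already normalized / residualized)
#' phenotype on the dosage of every variant within the cis window
#' `[tss - window, tss + window]` (1-based, fully closed) on the TSS
#' chromosome. Missing dosages are mean-imputed per variant at scan time
#' only. The best variant has the smallest nominal p; ties are broken by
#' distance to the TSS, then variant id.
#'
#' @param phenotype Named numeric vector (names = sample ids) or plain
#'   vector aligned with `gm$samples`.
#' @param gm A [genotype_matrix()].
#' @param tss List or one-row data frame with `chrom`, `tss` and
#'   optionally `strand` (distance sign: negative = upstream on the +
#'   strand).
#' @param window Cis window half-width in bases.
#' @return Object of class `cis_scan`: per-variant table (`slope`, `r2`,
#'   `p`, signed `dist`) and the best variant id.
#' @export
cis_scan <- function(phenotype, gm, tss, window = 1e6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(names(phenotype))) {
    if (!all(gm$samples %in% names(phenotype)))
      stop("phenotype missing values for some genotyped samples")
    phenotype <- phenotype[gm$samples]
  } else if (length(phenotype) != length(gm$samples)) {
    stop("phenotype length does not match sample count")
  }
  v <- gm$variants
  inwin <- v$chrom == tss$chrom & v$pos >= tss$tss - window & v$pos <= tss$tss + window
  if (!any(inwin)) stop("no variants in the cis window")
  v <- v[inwin, , drop = FALSE]
  X <- .impute_dosages(gm$dosages[, inwin, drop = FALSE])
  st <- .scan_stats(X, phenotype)
  strand <- if (!is.null(tss$strand)) tss$strand else "+"
  dist <- v$pos - tss$tss
  if (identical(strand, "-")) dist <- -dist
  tab <- data.frame(id = v$id, chrom = v$chrom, pos = v$pos, dist = dist,
                    slope = st$slope, r2 = st$r2, p = st$p,
                    row.names = NULL, stringsAsFactors = FALSE)
  cand <- which(!is.na(tab$p))
  if (!length(cand)) stop("no polymorphic variants in the cis window")
  best <- cand[order(tab$p[cand], abs(tab$dist[cand]), tab$id[cand])][1]
  structure(list(table = tab, best = tab$id[best], n = length(phenotype)),
            class = "cis_scan")
}

#' @export
print.cis_scan <- function(x, ...) {
  b <- x$table[x$table$id == x$best, ]
  cat(sprintf("Cis scan: %d variants, n = %d\n", nrow(x$table), x$n))
  cat(sprintf("  best: %s  slope %.4g  r2 %.4g  p %.3g\n",
              b$id, b$slope, b$r2, b$p))
  invisible(x)
}

#' Gene-level permutation significance with beta approximation
#'
#' Permutes the phenotype `R` times; the null statistic is the
#' per-replicate minimum nominal p over all cis variants, which accounts
#' for the multiplicity of the scan. The empirical p-value is
#' `(b + 1) / (R + 1)` with `b` the number of null minima at or below
#' the observed best nominal p. A Beta(a, b) distribution fitted to the
#' null minima by maximum likelihood (method-of-moments start, bounded
#' optimization, falling back to the moments estimate on
#' non-convergence) yields the smoothed p-value
#' `pbeta(p_obs, a, b)`.
#'
#' @inheritParams cis_scan
#' @param R Number of permutations (>= 100).
#' @param seed Optional integer seed.
#' @return Object of class `gene_perm`: `empirical_p`, `beta_p`, the
#'   fitted shapes, the observed scan, and the vector of null minima.
#' @export
gene_permutation_p <- function(phenotype, gm, tss, window = 1e6, R = 1000,
                               seed = NULL) {
  if (R < 100) stop("R must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  scan <- cis_scan(phenotype, gm, tss, window)
  obs <- min(scan$table$p, na.rm = TRUE)
  if (!is.null(names(phenotype))) phenotype <- phenotype[gm$samples]

  v <- gm$variants
  inwin <- v$chrom == tss$chrom & v$pos >= tss$tss - window & v$pos <= tss$tss + window
  X <- .impute_dosages(gm$dosages[, inwin, drop = FALSE])
  keep <- apply(X, 2, stats::var) > 0
  X <- X[, keep, drop = FALSE]
  n <- length(phenotype)
  Xs <- scale(X)
  Yp <- matrix(phenotype[c(replicate(R, sample.int(n)))], n, R)
  Ys <- scale(Yp)
  rmat <- crossprod(Xs, Ys) / (n - 1)
  r2 <- pmin(rmat^2, 1)
  tt <- sqrt(n - 2) * sqrt(r2) / sqrt(pmax(1 - r2, .Machine$double.eps))
  pmat <- 2 * stats::pt(tt, df = n - 2, lower.tail = FALSE)
  null_min <- apply(pmat, 2, min)

  empirical_p <- (sum(null_min <= obs) + 1) / (R + 1)
  if (stats::var(null_min) == 0)
    stop("degenerate permutation null: all minima identical")
  fit <- .fit_beta(null_min)
  beta_p <- stats::pbeta(obs, fit$shape1, fit$shape2)
  structure(list(empirical_p = empirical_p, beta_p = beta_p,
                 shape1 = fit$shape1, shape2 = fit$shape2,
                 beta_converged = fit$converged, R = R, scan = scan,
                 null_min = null_min, observed_p = obs),
            class = "gene_perm")
}

# Beta(a,b) fit: method-of-moments start, bounded ML refinement
.fit_beta <- function(x) {
  eps <- 1e-12
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x); v <- stats::var(x)
  v <- min(v, m * (1 - m) * (1 - 1e-8))
  common <- m * (1 - m) / v - 1
  start <- c(max(m * common, 1e-3), max((1 - m) * common, 1e-3))
  nll <- function(par) -sum(stats::dbeta(x, par[1], par[2], log = TRUE))
  opt <- tryCatch(
    stats::optim(start, nll, method = "L-BFGS-B",
                 lower = c(1e-6, 1e-6), upper = c(1e6, 1e6)),
    error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0)
    return(list(shape1 = start[1], shape2 = start[2], converged = FALSE))
  list(shape1 = opt$par[1], shape2 = opt$par[2], converged = TRUE)
}

#' @export
print.gene_perm <- function(x, ...) {
  cat(sprintf("Gene-level permutation significance (R = %d)\n", x$R))
  cat(sprintf("  best variant: %s  nominal p %.3g\n", x$scan$best, x$observed_p))
  cat(sprintf("  empirical p %.4g   beta-approximated p %.4g (a=%.3g, b=%.3g%s)\n",
              x$empirical_p, x$beta_p, x$shape1, x$shape2,
              if (x$beta_converged) "" else ", moments fallback"))
  invisible(x)
}

#' Benjamini-Hochberg gene selection
#'
#' Step-up FDR control at the given level on gene-level p-values.
#'
#' @param gene_p Named vector of p-values in `[0, 1]`.
#' @param level FDR level.
#' @return List with `selected` (gene names), `threshold` (largest
#'   selected p-value, 0 if none) and the vector of BH-adjusted
#'   p-values.
#' @export
fdr_select <- function(gene_p, level = 0.05) {
  if (length(gene_p) == 0) stop("empty p-value input")
  if (any(gene_p < 0 | gene_p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (is.null(names(gene_p))) names(gene_p) <- paste0("gene", seq_along(gene_p))
  padj <- stats::p.adjust(gene_p, method = "BH")
  sel <- names(gene_p)[padj <= level]
  threshold <- if (length(sel)) max(gene_p[sel]) else 0
  list(selected = sel, threshold = threshold, padj = padj)
}

#' Genotype-by-stimulation interaction test
#'
#' Fits expression on genotype, stimulation and their interaction with a
#' per-individual intercept. For a balanced two-condition paired design
#' the fixed per-individual intercepts reduce exactly to regressing the
#' within-individual expression difference (stim minus unstim) on
#' dosage: the slope of that regression is the interaction effect and
#' its t-test the interaction p-value. Condition is coded -1/2 (unstim)
#' and +1/2 (stim), so the condition-stratified slopes satisfy
#' `slope_cond = genotype_main +/- interaction / 2` exactly.
#'
#' @param pheno Data frame with columns `sample_id`, `condition`
#'   (`"unstim"` / `"stim"`) and `expr` (one row per sample and
#'   condition).
#' @param dosage Named numeric vector of dosages per sample.
#' @return Object of class `interaction_fit` with main effects, the
#'   interaction effect and p-value, and per-condition slopes and
#'   p-values from stratified regressions.
#' @export
interaction_test <- function(pheno, dosage) {
  need <- c("sample_id", "condition", "expr")
  if (!all(need %in% names(pheno))) stop("pheno needs columns sample_id, condition, expr")
  u <- pheno[pheno$condition == "unstim", ]
  s <- pheno[pheno$condition == "stim", ]
  m <- merge(u[c("sample_id", "expr")], s[c("sample_id", "expr")],
             by = "sample_id", suffixes = c("_unstim", "_stim"))
  m <- m[m$sample_id %in% names(dosage), ]
  n_dropped <- length(unique(pheno$sample_id)) - nrow(m)
  if (n_dropped > 0)
    warning(sprintf("%d unpaired or ungenotyped individuals dropped", n_dropped))
  if (nrow(m) < 3) stop("fewer than 3 paired individuals")
  g <- dosage[m$sample_id]
  if (stats::var(g) == 0)
    stop("genotype is constant: genotype and interaction terms inestimable")

  d <- m$expr_stim - m$expr_unstim
  fit_d <- stats::lm(d ~ g)
  sm_d <- summary(fit_d)$coefficients
  mean_y <- (m$expr_stim + m$expr_unstim) / 2
  fit_m <- stats::lm(mean_y ~ g)

  strat <- lapply(list(unstim = m$expr_unstim, stim = m$expr_stim), function(y) {
    f <- stats::lm(y ~ g)
    co <- summary(f)$coefficients
    list(slope = co["g", "Estimate"], p = co["g", "Pr(>|t|)"])
  })

  structure(list(
    genotype_main = unname(stats::coef(fit_m)["g"]),
    stimulation_main = unname(stats::coef(fit_d)["(Intercept)"]),
    interaction = sm_d["g", "Estimate"],
    interaction_p = sm_d["g", "Pr(>|t|)"],
    slope_unstim = strat$unstim$slope, p_unstim = strat$unstim$p,
    slope_stim = strat$stim$slope, p_stim = strat$stim$p,
    n = nrow(m), n_dropped = n_dropped
  ), class = "interaction_fit")
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("Genotype x stimulation interaction (n = %d pairs)\n", x$n))
  cat(sprintf("  interaction effect %.4g (p = %.3g)\n", x$interaction, x$interaction_p))
  cat(sprintf("  slope unstim %.4g (p = %.3g)   slope stim %.4g (p = %.3g)\n",
              x$slope_unstim, x$p_unstim, x$slope_stim, x$p_stim))
  invisible(x)
}

#' Storey pi1 replication estimate
#'
#' Estimates the proportion of true associations among replication
#' p-values: `pi0 = #(p > lambda) / ((1 - lambda) m)` clipped to
#' `[0, 1]`, and `pi1 = 1 - pi0`. Uses a single lambda by default; the
#' grid flag averages pi0 over `lambda = 0.2, 0.25, ..., 0.8`.
#'
#' @param p Vector of at least 20 p-values.
#' @param lambda Tuning threshold in (0, 1).
#' @param grid Average over a lambda grid instead of a single value?
#' @return Object of class `pi1_estimate` with `pi1`, `pi0`, `lambda`,
#'   `m`.
#' @export
pi1 <- function(p, lambda = 0.5, grid = FALSE) {
  if (length(p) < 20) stop("need at least 20 p-values")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  lambdas <- if (grid) seq(0.2, 0.8, by = 0.05) else lambda
  pi0s <- vapply(lambdas, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- min(max(mean(pi0s), 0), 1)
  structure(list(pi1 = 1 - pi0, pi0 = pi0, lambda = lambdas, m = length(p)),
            class = "pi1_estimate")
}

#' @export
print.pi1_estimate <- function(x, ...) {
  cat(sprintf("pi1 = %.3f (pi0 = %.3f) from m = %d p-values, lambda = %s\n",
              x$pi1, x$pi0, x$m,
              if (length(x$lambda) > 1) "grid" else format(x$lambda)))
  invisible(x)
}

#' LD r-squared between two variants
#'
#' Squared Pearson correlation of the dosage vectors over samples
#' non-missing at both variants.
#'
#' @param gm A [genotype_matrix()].
#' @param id1,id2 Variant ids.
#' @return r-squared.
#' @export
ld_r2 <- function(gm, id1, id2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  for (id in c(id1, id2))
    if (!id %in% gm$variants$id) stop("unknown variant id: ", id)
  x <- gm$dosages[, id1]
  y <- gm$dosages[, id2]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("monomorphic variant in LD computation")
  stats::cor(x, y)^2
}

#' Choose the expression-PC covariate count maximizing eGene yield
#'
#' Runs the full per-gene scan (inverse normal transform, residualize on
#' k expression PCs, cis scan with gene-level permutation p, BH
#' selection) for each candidate k and returns the k with the largest
#' count of FDR-significant genes; ties go to the smallest k.
#'
#' @param pheno_matrix Genes-by-samples expression matrix (rownames =
#'   genes, colnames = sample ids).
#' @param gm A [genotype_matrix()].
#' @param tss_table Data frame with `gene`, `chrom`, `tss`, `strand`.
#' @param ks Candidate PC counts.
#' @param window Cis window half-width.
#' @param R Permutations per gene.
#' @param level FDR level.
#' @param seed Optional integer seed.
#' @return List with `k`, `counts` (named by k), and per-k selected
#'   genes.
#' @export
choose_covariate_count <- function(pheno_matrix, gm, tss_table, ks,
                                   window = 1e6, R = 200, level = 0.05,
                                   seed = NULL) {
  if (length(ks) == 0) stop("candidate list must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  pheno_matrix <- as.matrix(pheno_matrix)
  genes <- intersect(rownames(pheno_matrix), tss_table$gene)
  if (!length(genes)) stop("no genes shared between phenotype matrix and TSS table")
  ks <- sort(unique(as.integer(ks)))
  counts <- integer(length(ks)); names(counts) <- ks
  selected <- vector("list", length(ks)); names(selected) <- ks
  for (i in seq_along(ks)) {
    k <- ks[i]
    pcs <- compute_pcs(t(pheno_matrix), k)
    gene_p <- vapply(genes, function(g) {
      y <- inverse_normal_transform(pheno_matrix[g, gm$samples])
      y <- residualize(y, if (k > 0) pcs else NULL)
      names(y) <- gm$samples
      tss <- tss_table[tss_table$gene == g, ]
      gene_permutation_p(y, gm, tss, window = window, R = R)$beta_p
    }, numeric(1))
    sel <- fdr_select(gene_p, level)
    counts[i] <- length(sel$selected)
    selected[[i]] <- sel$selected
  }
  best <- ks[which.max(counts)]  # which.max takes the first (smallest k) on ties
  list(k = best, counts = counts, selected = selected)
}
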