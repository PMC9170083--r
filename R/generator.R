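#' Generator configuration for synthetic HLA expression cohorts
#'
#' Defines the variance-components model used to simulate allelic HLA
#' class I expression. On the natural-log scale, the expression of one
#' allele copy in one sample and condition is
#' \deqn{\ln(tpm) = \mu_{locus} + \alpha_{allele} + g_{individual} +
#'   h_{haplotype} + [\,stim\,] + \sum_v \beta_v d_v + \epsilon}
#' where \eqn{\alpha \sim N(0, \sigma_A^2)} is a fixed per-allele-name
#' effect shared by all carriers, \eqn{g \sim N(0, \sigma_G^2)} is a
#' shared per-individual factor producing coordinated biallelic
#' expression, \eqn{h \sim N(0, \sigma_H^2)} is a per-founder-haplotype
#' factor, \eqn{d_v} is the dosage of a planted cis variant with effect
#' \eqn{\beta_v}, and \eqn{\epsilon \sim N(0, \sigma_E^2)} is drawn fresh
#' per record. Under stimulation the additive shift
#' \code{stim_logfold[locus] + s_allele} is added, with
#' \eqn{s \sim N(0, \sigma_S^2)} drawn once per allele name.
#'
#' All effect parameters are on the natural-log scale, which makes the
#' within-individual allelic-balance statistic exactly
#' \eqn{1/(1+e^{|d|})} for a log-difference \eqn{d}.
#'
#' @param n_individuals Number of individuals (>= 0).
#' @param loci Character vector of locus names, e.g. `c("A","B","C")`.
#' @param allele_pool Named list, one element per locus: a named numeric
#'   vector of allele frequencies (names are two-field allele names such
#'   as `"B*18:01"`). Frequencies must sum to 1 within 1e-9. May be
#'   omitted when `haplotype_table` is supplied.
#' @param haplotype_table Optional data frame defining founder
#'   haplotypes: one column per locus holding allele names, plus a
#'   `freq` column summing to 1. When present, individuals draw two
#'   haplotypes i.i.d. from it (overriding independent allele sampling)
#'   and marker alleles segregate with them.
#' @param mu_locus Named numeric, natural-log mean tpm per locus.
#' @param sigma_A SD of fixed per-allele effects (ln scale).
#' @param sigma_G SD of the shared per-individual factor.
#' @param sigma_H SD of the per-haplotype factor (requires
#'   `haplotype_table`).
#' @param sigma_E SD of the per-measurement residual.
#' @param stim_logfold Named numeric, per-locus additive ln-scale shift
#'   under stimulation (default 0).
#' @param sigma_S SD of the per-allele deviation of the stimulation
#'   shift.
#' @param stim_sigma_A,stim_sigma_E Optional alternative per-allele
#'   effect SD and residual SD used under stimulation. When
#'   `stim_sigma_A` is set an independent per-allele effect with that SD
#'   replaces `alpha` in stimulated records (a dispersion-calibration
#'   device; by default `alpha` is shared across conditions, the paired
#'   design).
#' @param eqtl_specs Optional data frame with columns `marker_id`
#'   (`"chrom:pos:ref:alt"`), `locus`, `beta` (ln-scale effect per
#'   dosage unit) planting cis-eQTL effects.
#' @param markers Optional data frame of marker variants with columns
#'   `chrom`, `pos` (1-based, strictly increasing within chromosome),
#'   `ref`, `alt`.
#' @param marker_alleles Binary matrix, rows aligned to
#'   `haplotype_table` rows, columns to `markers` rows: the allele each
#'   founder haplotype carries at each marker.
#' @param allele_effect_mode `"shared"` (default): allele effects drawn
#'   once per allele name and shared by all carriers. `"fresh"`: an
#'   independent effect per carried copy, useful for large-sample
#'   closed-form checks.
#' @param seed Integer seed in `[0, 2^31 - 16]`; a single seeded stream
#'   drives all draws.
#'
#' @return An object of class `hla_generator_config`.
#' @seealso [sample_cohort()], [simulate_expression()],
#'   [simulate_genotypes()]
#' @export
generator_config <- function(n_individuals,
                             loci,
                             allele_pool = NULL,
                             haplotype_table = NULL,
                             mu_locus = NULL,
                             sigma_A = 0.10,
                             sigma_G = 0.40,
                             sigma_H = 0,
                             sigma_E = 0.08,
                             stim_logfold = NULL,
                             sigma_S = 0,
                             stim_sigma_A = NULL,
                             stim_sigma_E = NULL,
                             eqtl_specs = NULL,
                             markers = NULL,
                             marker_alleles = NULL,
                             allele_effect_mode = c("shared", "fresh"),
                             seed = 1L) {
  allele_effect_mode <- match.arg(allele_effect_mode)
  stopifnot(is.character(loci), length(loci) >= 1, !anyDuplicated(loci))
  if (!is.numeric(n_individuals) || length(n_individuals) != 1 ||
      n_individuals < 0 || n_individuals != floor(n_individuals))
    stop("n_individuals must be a single non-negative integer")
  if (!is.numeric(seed) || length(seed) != 1 || seed < 0 ||
      seed > 2^31 - 16 || seed != floor(seed))
    stop("seed must be an integer in [0, 2^31 - 16]")
  for (s in c(sigma_A, sigma_G, sigma_H, sigma_E, sigma_S,
              stim_sigma_A, stim_sigma_E))
    if (!is.null(s) && (!is.numeric(s) || length(s) != 1 || s < 0))
      stop("all SD parameters must be single non-negative numbers")

  if (is.null(mu_locus)) mu_locus <- stats::setNames(rep(log(1000), length(loci)), loci)
  if (is.null(names(mu_locus)) || !all(loci %in% names(mu_locus)))
    stop("mu_locus must be named for every configured locus")
  mu_locus <- mu_locus[loci]

  if (is.null(stim_logfold)) stim_logfold <- stats::setNames(rep(0, length(loci)), loci)
  if (is.null(names(stim_logfold)) || !all(loci %in% names(stim_logfold)))
    stop("stim_logfold must be named for every configured locus")
  stim_logfold <- stim_logfold[loci]

  if (is.null(allele_pool) && is.null(haplotype_table))
    stop("either allele_pool or haplotype_table is required")

  if (!is.null(allele_pool)) {
    if (!all(loci %in% names(allele_pool)))
      stop("allele_pool must have one element per configured locus")
    for (loc in loci) {
      pool <- allele_pool[[loc]]
      if (length(pool) == 0)
        stop(sprintf("empty allele pool for locus %s", loc))
      if (is.null(names(pool)) || any(!nzchar(names(pool))))
        stop(sprintf("allele pool for locus %s must be a named frequency vector", loc))
      if (any(pool < 0) || abs(sum(pool) - 1) > 1e-9)
        stop(sprintf("allele frequencies at locus %s must be non-negative and sum to 1", loc))
    }
  }

  if (!is.null(haplotype_table)) {
    if (!is.data.frame(haplotype_table) ||
        !all(c(loci, "freq") %in% names(haplotype_table)))
      stop("haplotype_table needs one column per locus plus 'freq'")
    if (any(haplotype_table$freq < 0) ||
        abs(sum(haplotype_table$freq) - 1) > 1e-9)
      stop("haplotype frequencies must be non-negative and sum to 1")
    if (!is.null(allele_pool)) {
      for (loc in loci) {
        extra <- setdiff(haplotype_table[[loc]], names(allele_pool[[loc]]))
        if (length(extra))
          stop(sprintf("haplotype alleles absent from pool at locus %s: %s",
                       loc, paste(extra, collapse = ", ")))
      }
    }
  } else if (sigma_H > 0) {
    stop("sigma_H > 0 requires a haplotype_table")
  }

  if (!is.null(markers)) {
    if (is.null(haplotype_table))
      stop("markers require a haplotype_table carrying their alleles")
    if (!is.data.frame(markers) ||
        !all(c("chrom", "pos", "ref", "alt") %in% names(markers)))
      stop("markers needs columns chrom, pos, ref, alt")
    for (chr in unique(markers$chrom)) {
      p <- markers$pos[markers$chrom == chr]
      if (any(diff(p) <= 0))
        stop("marker positions must be strictly increasing per chromosome")
    }
    if (is.null(marker_alleles) ||
        !is.matrix(marker_alleles) ||
        nrow(marker_alleles) != nrow(haplotype_table) ||
        ncol(marker_alleles) != nrow(markers) ||
        !all(marker_alleles %in% c(0, 1)))
      stop("marker_alleles must be a binary haplotypes x markers matrix")
    markers$id <- variant_id(markers$chrom, markers$pos, markers$ref, markers$alt)
    if (anyDuplicated(markers$id)) stop("duplicate marker ids")
  }

  if (!is.null(eqtl_specs)) {
    if (!is.data.frame(eqtl_specs) ||
        !all(c("marker_id", "locus", "beta") %in% names(eqtl_specs)))
      stop("eqtl_specs needs columns marker_id, locus, beta")
    if (is.null(markers) || !all(eqtl_specs$marker_id %in% markers$id))
      stop("eqtl_specs reference unknown marker ids")
    if (!all(eqtl_specs$locus %in% loci))
      stop("eqtl_specs reference unknown loci")
  }

  structure(list(
    n_individuals = as.integer(n_individuals),
    loci = loci,
    allele_pool = allele_pool,
    haplotype_table = haplotype_table,
    mu_locus = mu_locus,
    sigma_A = sigma_A, sigma_G = sigma_G, sigma_H = sigma_H,
    sigma_E = sigma_E, sigma_S = sigma_S,
    stim_logfold = stim_logfold,
    stim_sigma_A = stim_sigma_A, stim_sigma_E = stim_sigma_E,
    eqtl_specs = eqtl_specs,
    markers = markers,
    marker_alleles = marker_alleles,
    allele_effect_mode = allele_effect_mode,
    seed = as.integer(seed)
  ), class = "hla_generator_config")
}

#' Canonical variant identifier
#'
#' @param chrom,pos,ref,alt Vectors describing biallelic variants.
#' @return Character vector `"chrom:pos:ref:alt"`.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' @export
print.hla_generator_config <- function(x, ...) {
  cat("HLA cohort generator configuration\n")
  cat(sprintf("  individuals: %d   loci: %s\n", x$n_individuals,
              paste(x$loci, collapse = ", ")))
  cat(sprintf("  sigma_A=%.3g sigma_G=%.3g sigma_H=%.3g sigma_E=%.3g sigma_S=%.3g\n",
              x$sigma_A, x$sigma_G, x$sigma_H, x$sigma_E, x$sigma_S))
  cat(sprintf("  allele effects: %s; haplotype table: %s; markers: %d; seed: %d\n",
              x$allele_effect_mode,
              if (is.null(x$haplotype_table)) "none" else
                sprintf("%d founders", nrow(x$haplotype_table)),
              if (is.null(x$markers)) 0L else nrow(x$markers),
              x$seed))
  invisible(x)
}

# condition -> seed offset for the residual stream; cohort-level draws use
# the base seed, so the paired structure (alpha, g, h shared across
# conditions) is automatic while residuals are fresh per condition.
.condition_offsets <- c(fresh = 1L, unstim = 2L, stim = 3L)

#' Sample a synthetic cohort
#'
#' Draws individuals and all condition-invariant random effects from the
#' generator configuration. Draw order is fixed for reproducibility:
#' haplotype/allele assignment, per-allele effects (lexicographic allele
#' name order; or per carried copy in `"fresh"` mode), per-haplotype
#' effects, per-individual factors, stimulation-specific allele terms.
#' Measurement residuals are drawn later, in [simulate_expression()].
#'
#' @param config A [generator_config()].
#' @return An object of class `hla_cohort`: individuals with their two
#'   haplotypes, the carried allele names per locus, and all realized
#'   ln-scale effects.
#' @export
sample_cohort <- function(config) {
  stopifnot(inherits(config, "hla_generator_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  loci <- config$loci
  sample_ids <- if (n > 0) sprintf("S%04d", seq_len(n)) else character()

  hap1 <- hap2 <- rep(NA_integer_, n)
  alleles <- vector("list", length(loci))
  names(alleles) <- loci

  if (!is.null(config$haplotype_table)) {
    ht <- config$haplotype_table
    if (n > 0) {
      hap1 <- sample.int(nrow(ht), n, replace = TRUE, prob = ht$freq)
      hap2 <- sample.int(nrow(ht), n, replace = TRUE, prob = ht$freq)
    }
    for (loc in loci)
      alleles[[loc]] <- cbind(ht[[loc]][hap1], ht[[loc]][hap2])
  } else {
    for (loc in loci) {
      pool <- config$allele_pool[[loc]]
      a1 <- if (n > 0) sample(names(pool), n, replace = TRUE, prob = pool) else character()
      a2 <- if (n > 0) sample(names(pool), n, replace = TRUE, prob = pool) else character()
      alleles[[loc]] <- cbind(a1, a2)
    }
  }
  if (n == 0) for (loc in loci) alleles[[loc]] <- matrix(character(), 0, 2)

  carried <- sort(unique(unlist(lapply(alleles, as.vector))))
  allele_effects <- stats::setNames(stats::rnorm(length(carried), 0, config$sigma_A), carried)

  fresh_effects <- NULL
  if (config$allele_effect_mode == "fresh") {
    fresh_effects <- lapply(loci, function(loc)
      matrix(stats::rnorm(2L * n, 0, config$sigma_A), n, 2))
    names(fresh_effects) <- loci
  }

  hap_effects <- if (!is.null(config$haplotype_table))
    stats::rnorm(nrow(config$haplotype_table), 0, config$sigma_H) else numeric()

  indiv_factors <- stats::setNames(stats::rnorm(n, 0, config$sigma_G), sample_ids)

  stim_dev <- stats::setNames(stats::rnorm(length(carried), 0, config$sigma_S), carried)
  stim_allele_effects <- NULL
  stim_fresh_effects <- NULL
  if (!is.null(config$stim_sigma_A)) {
    stim_allele_effects <- stats::setNames(
      stats::rnorm(length(carried), 0, config$stim_sigma_A), carried)
    if (config$allele_effect_mode == "fresh") {
      stim_fresh_effects <- lapply(loci, function(loc)
        matrix(stats::rnorm(2L * n, 0, config$stim_sigma_A), n, 2))
      names(stim_fresh_effects) <- loci
    }
  }

  structure(list(
    config = config,
    sample_ids = sample_ids,
    hap1 = hap1, hap2 = hap2,
    alleles = alleles,
    allele_effects = allele_effects,
    fresh_effects = fresh_effects,
    hap_effects = hap_effects,
    indiv_factors = indiv_factors,
    stim_dev = stim_dev,
    stim_allele_effects = stim_allele_effects,
    stim_fresh_effects = stim_fresh_effects
  ), class = "hla_cohort")
}

#' @export
print.hla_cohort <- function(x, ...) {
  cat(sprintf("Synthetic HLA cohort: %d individuals, loci %s\n",
              length(x$sample_ids), paste(x$config$loci, collapse = ", ")))
  cat(sprintf("  %d distinct carried alleles; haplotype table: %s\n",
              length(x$allele_effects),
              if (is.null(x$config$haplotype_table)) "none" else
                sprintf("%d founders", nrow(x$config$haplotype_table))))
  invisible(x)
}

# dosage matrix (individuals x markers) implied by carried haplotypes
.cohort_dosages <- function(cohort) {
  cfg <- cohort$config
  if (is.null(cfg$markers)) return(NULL)
  ma <- cfg$marker_alleles
  d <- ma[cohort$hap1, , drop = FALSE] + ma[cohort$hap2, , drop = FALSE]
  dimnames(d) <- list(cohort$sample_ids, cfg$markers$id)
  d
}

#' Simulate an allelic expression table
#'
#' Realizes one condition of the variance-components model for every
#' allele copy carried by the cohort. Residuals are drawn from a stream
#' seeded by the cohort seed plus a per-condition offset, so repeated
#' calls are reproducible and conditions share all individual-level
#' effects (the paired design) while having independent residuals.
#'
#' @param cohort A cohort from [sample_cohort()].
#' @param condition One of `"fresh"`, `"unstim"`, `"stim"`.
#' @return A data frame of expression records with columns `sample_id`,
#'   `locus`, `allele`, `copy`, `condition`, `tpm` (two records per
#'   sample, locus and condition).
#' @export
simulate_expression <- function(cohort, condition = c("unstim", "fresh", "stim")) {
  stopifnot(inherits(cohort, "hla_cohort"))
  condition <- match.arg(condition)
  cfg <- cohort$config
  set.seed(cfg$seed + .condition_offsets[[condition]])

  n <- length(cohort$sample_ids)
  loci <- cfg$loci
  if (n == 0)
    return(data.frame(sample_id = character(), locus = character(),
                      allele = character(), copy = integer(),
                      condition = character(), tpm = numeric(),
                      stringsAsFactors = FALSE))
  dos <- .cohort_dosages(cohort)
  stim <- condition == "stim"
  sigma_e <- if (stim && !is.null(cfg$stim_sigma_E)) cfg$stim_sigma_E else cfg$sigma_E

  out <- vector("list", length(loci))
  for (j in seq_along(loci)) {
    loc <- loci[j]
    anames <- cohort$alleles[[loc]]          # n x 2
    if (cfg$allele_effect_mode == "fresh") {
      alpha <- if (stim && !is.null(cohort$stim_fresh_effects))
        cohort$stim_fresh_effects[[loc]] else cohort$fresh_effects[[loc]]
    } else {
      eff <- if (stim && !is.null(cohort$stim_allele_effects))
        cohort$stim_allele_effects else cohort$allele_effects
      alpha <- matrix(eff[anames], n, 2)
    }
    h <- if (length(cohort$hap_effects))
      cbind(cohort$hap_effects[cohort$hap1], cohort$hap_effects[cohort$hap2])
    else matrix(0, n, 2)

    ln <- cfg$mu_locus[[loc]] + alpha + h +
      matrix(cohort$indiv_factors, n, 2)
    if (stim) {
      ln <- ln + cfg$stim_logfold[[loc]] + matrix(cohort$stim_dev[anames], n, 2)
    }
    if (!is.null(cfg$eqtl_specs)) {
      specs <- cfg$eqtl_specs[cfg$eqtl_specs$locus == loc, , drop = FALSE]
      for (k in seq_len(nrow(specs)))
        ln <- ln + specs$beta[k] * dos[, specs$marker_id[k]]
    }
    ln <- ln + matrix(stats::rnorm(2L * n, 0, sigma_e), n, 2)

    out[[j]] <- data.frame(
      sample_id = rep(cohort$sample_ids, 2L),
      locus = loc,
      allele = c(anames[, 1], anames[, 2]),
      copy = rep(1:2, each = n),
      condition = condition,
      tpm = exp(c(ln[, 1], ln[, 2])),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$sample_id, res$locus, res$copy), , drop = FALSE]
}

#' Simulate a genotype matrix from carried haplotypes
#'
#' The dosage of each marker is the sum of the two carried haplotypes'
#' binary marker alleles, so LD among markers and with HLA allele names
#' arises from haplotype sharing alone.
#'
#' @param cohort A cohort from [sample_cohort()] whose configuration
#'   defines markers.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(cohort) {
  stopifnot(inherits(cohort, "hla_cohort"))
  cfg <- cohort$config
  if (is.null(cfg$markers)) stop("no markers configured for this cohort")
  dos <- .cohort_dosages(cohort)
  genotype_matrix(cohort$sample_ids, cfg$markers[c("chrom", "pos", "ref", "alt", "id")], dos)
}

#' Extract an HLA typing table from a cohort
#'
#' @param cohort A cohort from [sample_cohort()].
#' @return Data frame with `sample_id` and `<locus>_1`, `<locus>_2`
#'   allele-name columns (unordered genotype; copy order as simulated).
#' @export
cohort_typings <- function(cohort) {
  stopifnot(inherits(cohort, "hla_cohort"))
  out <- data.frame(sample_id = cohort$sample_ids, stringsAsFactors = FALSE)
  for (loc in cohort$config$loci) {
    out[[paste0(loc, "_1")]] <- cohort$alleles[[loc]][, 1]
    out[[paste0(loc, "_2")]] <- cohort$alleles[[loc]][, 2]
  }
  out
}
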