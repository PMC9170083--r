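#' Demo run configuration
#'
#' A ready-made pipeline configuration mirroring the shape of a typical
#' PBMC allelic-expression study: 63 individuals typed at HLA-A, -B and
#' -C, 15 alleles per locus segregating on 30 founder haplotypes (the
#' three most frequent ones shared widely enough to group carriers),
#' two culture conditions with 56 individuals stimulated, cis markers on
#' chromosome 6 including allele-tagging coding variants and one planted
#' regulatory eQTL, 1000 permutation replicates and a 5% FDR.
#'
#' @param seed Integer seed.
#' @param n_individuals Cohort size.
#' @param R Permutation replicates.
#' @return A run-configuration list for [run_pipeline()].
#' @export
demo_run_config <- function(seed = 1L, n_individuals = 63L, R = 1000L) {
  loci <- c("A", "B", "C")
  pools <- list(
    A = c("A*01:01", "A*02:01", "A*03:01", "A*11:01", "A*24:02", "A*26:01",
          "A*29:02", "A*31:01", "A*32:01", "A*33:03", "A*68:01", "A*23:01",
          "A*25:01", "A*30:01", "A*66:01"),
    B = c("B*07:02", "B*08:01", "B*18:01", "B*15:01", "B*44:02", "B*44:03",
          "B*35:01", "B*40:01", "B*51:01", "B*57:01", "B*13:02", "B*14:02",
          "B*27:05", "B*56:01", "B*49:01"),
    C = c("C*01:02", "C*03:03", "C*03:04", "C*04:01", "C*05:01", "C*06:02",
          "C*07:01", "C*07:02", "C*08:02", "C*12:03", "C*14:02", "C*15:02",
          "C*16:01", "C*02:02", "C*17:01"))
  drb1 <- c("DRB1*03:01", "DRB1*15:01", "DRB1*07:01", "DRB1*04:01",
            "DRB1*01:01", "DRB1*11:01", "DRB1*13:01")

  set.seed(seed)
  n_hap <- 30L
  ht <- data.frame(
    A = c("A*01:01", "A*03:01", "A*02:01",
          sample(pools$A, n_hap - 3, replace = TRUE)),
    B = c("B*08:01", "B*07:02", "B*07:02",
          sample(pools$B, n_hap - 3, replace = TRUE)),
    C = c("C*07:01", "C*07:02", "C*07:02",
          sample(pools$C, n_hap - 3, replace = TRUE)),
    DRB1 = c("DRB1*03:01", "DRB1*15:01", "DRB1*15:01",
             sample(drb1, n_hap - 3, replace = TRUE)),
    stringsAsFactors = FALSE)
  w <- c(0.12, 0.08, 0.06, rep(NA, n_hap - 3))
  rest <- stats::rexp(n_hap - 3) + 0.2
  w[-(1:3)] <- 0.74 * rest / sum(rest)
  ht$freq <- w
  ht$label <- paste0("H", sprintf("%02d", seq_len(n_hap)))

  # chr6 markers spanning the class I region; random founder alleles,
  # plus coding tags for two alleles and one planted regulatory variant
  n_rand <- 36L
  pos <- sort(sample(seq(29900000L, 31400000L, by = 500L), n_rand))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_rand, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  ma <- matrix(rbinom(n_hap * n_rand, 1, stats::runif(n_rand, 0.1, 0.5)),
               n_hap, n_rand, byrow = TRUE)
  markers <- data.frame(chrom = "6", pos = pos, ref = ref, alt = alt,
                        stringsAsFactors = FALSE)
  # coding tags: allele = 1 exactly on haplotypes carrying the HLA allele
  tag <- function(locus, allele, pos) {
    markers <<- rbind(markers, data.frame(chrom = "6", pos = pos, ref = "G",
                                          alt = "A", stringsAsFactors = FALSE))
    ma <<- cbind(ma, as.integer(ht[[locus]] == allele))
  }
  tag("B", "B*08:01", 31324201L)
  tag("C", "C*07:01", 31237001L)
  # planted regulatory eQTL upstream of HLA-C
  markers <- rbind(markers, data.frame(chrom = "6", pos = 31243785L, ref = "G",
                                       alt = "T", stringsAsFactors = FALSE))
  ma <- cbind(ma, rbinom(n_hap, 1, 0.4))
  ord <- order(markers$pos)
  markers <- markers[ord, , drop = FALSE]
  ma <- ma[, ord, drop = FALSE]
  keep <- !duplicated(markers$pos)
  markers <- markers[keep, , drop = FALSE]
  ma <- ma[, keep, drop = FALSE]
  eqtl_specs <- data.frame(marker_id = variant_id("6", 31243785L, "G", "T"),
                           locus = "C", beta = 0.35, stringsAsFactors = FALSE)

  sig_tot2 <- 0.10^2 + 0.40^2 + 0.15^2 + 0.08^2
  mu <- log(c(A = 866, B = 1870, C = 1238)) - sig_tot2 / 2
  gen <- generator_config(
    n_individuals = n_individuals, loci = loci,
    allele_pool = lapply(pools, function(a) stats::setNames(rep(1 / length(a), length(a)), a)),
    haplotype_table = ht, mu_locus = mu,
    sigma_A = 0.10, sigma_G = 0.40, sigma_H = 0.15, sigma_E = 0.08,
    stim_logfold = log(c(A = 2.5, B = 2.04, C = 2.11)), sigma_S = 0.10,
    stim_sigma_A = 0.06, stim_sigma_E = 0.035,
    eqtl_specs = eqtl_specs, markers = markers, marker_alleles = ma,
    seed = seed)

  list(
    generator = gen,
    stages = c("simulate", "summary", "ase", "haplo", "eqtl"),
    thresholds = list(qc = qc_thresholds(), fdr_level = 0.05, permutations = R),
    n_stimulated = min(56L, n_individuals),
    n_expr_pcs = 2L,
    common_haplotype = "H01",
    tss = data.frame(gene = c("A", "B", "C"), chrom = "6",
                     tss = c(29910247L, 31324965L, 31236526L),
                     strand = c("+", "-", "-"), stringsAsFactors = FALSE),
    window = 1e6,
    seed = seed
  )
}

.pipe_log <- function(msg, logfile = NULL, verbose = TRUE) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  if (verbose) message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

.hash_file <- function(path) unname(tools::md5sum(path))

#' Run the full synthetic analysis pipeline
#'
#' Executes the configured stages in dependency order: simulate (cohort,
#' allelic expression tables, VCF genotypes, truth file), summary (locus
#' means, fold variation, stimulation fold change), ase (permutation
#' test of median ASE and paired condition test), haplo (haplotype
#' assignment and shared-versus-second regression contrast), eqtl
#' (variant QC, normalized cis scan with gene-level permutation
#' significance, BH selection, genotype-by-stimulation interaction).
#' Every output file is recorded in a JSON manifest with its md5 hash;
#' rerunning with the same configuration and seed reproduces the hashes.
#'
#' @param config A configuration list as from [demo_run_config()], or a
#'   path to a YAML file (see [read_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @param verbose Emit progress messages to stderr?
#' @return The run manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop("config must carry a seed")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "pipeline.log")
  if (file.exists(logfile)) unlink(logfile)
  stages <- config$stages
  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("hlaase")),
                   stages = list(), files = list())
  out <- function(name) file.path(out_dir, name)
  record <- function(name) {
    manifest$files[[name]] <<- list(path = out(name), md5 = .hash_file(out(name)))
  }
  finish_stage <- function(stage, status) {
    manifest$stages[[stage]] <<- status
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  }

  env <- new.env()
  run_stage <- function(stage, fun) {
    if (!stage %in% stages) return(invisible())
    .pipe_log(sprintf("stage %s: start", stage), logfile, verbose)
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) { manifest$stages[[stage]] <<- paste("failed:", conditionMessage(e)); FALSE })
    if (!ok) {
      finish_stage(stage, manifest$stages[[stage]])
      stop(sprintf("stage %s failed; partial manifest written (%s)",
                   stage, manifest$stages[[stage]]))
    }
    finish_stage(stage, "ok")
    .pipe_log(sprintf("stage %s: done", stage), logfile, verbose)
  }

  run_stage("simulate", function() {
    gen <- config$generator
    if (!inherits(gen, "hla_generator_config"))
      gen <- do.call(generator_config, gen)
    env$cohort <- sample_cohort(gen)
    env$expr_unstim <- simulate_expression(env$cohort, "unstim")
    stim_all <- simulate_expression(env$cohort, "stim")
    n_stim <- min(config$n_stimulated %||% length(env$cohort$sample_ids),
                  length(env$cohort$sample_ids))
    stim_ids <- sort(env$cohort$sample_ids)[seq_len(n_stim)]
    env$expr_stim <- stim_all[stim_all$sample_id %in% stim_ids, ]
    write_expression_table(env$expr_unstim, out("expression_unstim.tsv")); record("expression_unstim.tsv")
    write_expression_table(env$expr_stim, out("expression_stim.tsv")); record("expression_stim.tsv")
    if (!is.null(gen$markers)) {
      env$gm <- simulate_genotypes(env$cohort)
      write_vcf_minimal(env$gm, out("genotypes.vcf")); record("genotypes.vcf")
    }
    truth <- list(
      seed = gen$seed,
      sigma = list(A = gen$sigma_A, G = gen$sigma_G, H = gen$sigma_H,
                   E = gen$sigma_E, S = gen$sigma_S),
      mu_locus = as.list(gen$mu_locus),
      stim_logfold = as.list(gen$stim_logfold),
      eqtl_specs = gen$eqtl_specs,
      allele_effects = as.list(env$cohort$allele_effects),
      indiv_factors = as.list(env$cohort$indiv_factors),
      hap_effects = env$cohort$hap_effects)
    jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    record("truth.json")
  })

  run_stage("summary", function() {
    ls_tab <- locus_summary(env$expr_unstim, "unstim")
    utils::write.table(ls_tab, out("locus_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("locus_summary.tsv")
    fv <- rbind(fold_variation(env$expr_unstim, "unstim", "mean"),
                fold_variation(env$expr_unstim, "unstim", "median"))
    utils::write.table(fv, out("fold_variation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("fold_variation.tsv")
    if (nrow(env$expr_stim)) {
      fu <- suppressWarnings(fold_upregulation(env$expr_unstim, env$expr_stim))
      utils::write.table(fu$per_locus, out("fold_upregulation.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      record("fold_upregulation.tsv")
    }
  })

  run_stage("ase", function() {
    R <- config$thresholds$permutations %||% 1000
    pt <- permutation_test_median_ase(env$expr_unstim, R = R,
                                      seed = config$seed + 11L)
    report <- list(condition = "unstim", R = R, per_locus = pt$table,
                   replicate_median_quantiles = apply(pt$replicate_medians, 2,
                     stats::quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
    if (nrow(env$expr_stim)) {
      au <- ase_table(env$expr_unstim)
      as_ <- ase_table(env$expr_stim)
      report$paired <- lapply(intersect(unique(au$locus), unique(as_$locus)),
        function(loc) suppressWarnings(paired_condition_test(au, as_, loc)))
    }
    jsonlite::write_json(report, out("ase_report.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    record("ase_report.json")
  })

  run_stage("haplo", function() {
    gen <- env$cohort$config
    if (is.null(gen$haplotype_table)) return(invisible())
    ref <- gen$haplotype_table[c(gen$loci, "freq")]
    ref$label <- gen$haplotype_table$label %||% paste0("H", sprintf("%02d", seq_len(nrow(ref))))
    asg <- assign_haplotypes(cohort_typings(env$cohort), ref)
    common <- config$common_haplotype %||% ref$label[which.max(ref$freq)]
    fits <- shared_vs_second_contrast(env$expr_unstim, asg, common,
                                      condition = "unstim")
    # both regression orientations for each locus pair
    rev_fits <- fits
    rev_fits[c("locus_x", "locus_y")] <- fits[c("locus_y", "locus_x")]
    both <- rbind(
      cbind(fits, orientation = "forward"),
      cbind(do.call(rbind, lapply(seq_len(nrow(fits)), function(i) {
        f <- tryCatch(interlocus_regression(env$expr_unstim, asg, common,
                        c(fits$locus_y[i], fits$locus_x[i]), "unstim"),
                      error = function(e) NULL)
        data.frame(haplotype = common, locus_x = fits$locus_y[i],
                   locus_y = fits$locus_x[i],
                   se_common = if (is.null(f)) NA else f$residual_se,
                   se_second = NA, n = if (is.null(f)) NA else f$n,
                   stringsAsFactors = FALSE)
      })), orientation = "reverse"))
    utils::write.table(both, out("haplotype_fits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("haplotype_fits.tsv")
  })

  run_stage("eqtl", function() {
    if (is.null(env$gm)) stop("eqtl stage requires simulated genotypes")
    qc <- qc_filter_variants(env$gm, config$thresholds$qc %||% qc_thresholds())
    gm <- qc$genotypes
    utils::write.table(qc$log, out("variant_qc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("variant_qc.tsv")
    tss <- config$tss
    R <- config$thresholds$permutations %||% 1000
    k <- config$n_expr_pcs %||% 0L

    # gene-level phenotype: total tpm over the two allele copies
    e <- env$expr_unstim
    tot <- tapply(e$tpm, list(e$locus, e$sample_id), sum)
    pheno_matrix <- tot[, gm$samples, drop = FALSE]
    pcs <- if (k > 0) compute_pcs(t(pheno_matrix), k) else NULL

    rows <- list(); inter <- list()
    for (g in intersect(rownames(pheno_matrix), tss$gene)) {
      y <- residualize(inverse_normal_transform(pheno_matrix[g, ]), pcs)
      names(y) <- colnames(pheno_matrix)
      gp <- gene_permutation_p(y, gm, tss[tss$gene == g, ],
                               window = config$window %||% 1e6, R = R,
                               seed = config$seed + 23L)
      b <- gp$scan$table[gp$scan$table$id == gp$scan$best, ]
      rows[[g]] <- data.frame(gene = g, best_variant = gp$scan$best,
                              slope = b$slope, r2 = b$r2, nominal_p = b$p,
                              empirical_p = gp$empirical_p, beta_p = gp$beta_p,
                              R = R, stringsAsFactors = FALSE)
      es <- env$expr_stim
      if (nrow(es)) {
        tot_s <- tapply(es$tpm, list(es$locus, es$sample_id), sum)
        shared <- intersect(colnames(tot_s), colnames(pheno_matrix))
        ph <- rbind(
          data.frame(sample_id = shared, condition = "unstim",
                     expr = inverse_normal_transform(pheno_matrix[g, shared])),
          data.frame(sample_id = shared, condition = "stim",
                     expr = inverse_normal_transform(tot_s[g, shared])))
        dos <- gm$dosages[, gp$scan$best]
        it <- tryCatch(suppressWarnings(interaction_test(ph, dos)),
                       error = function(e) NULL)
        if (!is.null(it))
          inter[[g]] <- data.frame(gene = g, variant = gp$scan$best,
                                   genotype_main = it$genotype_main,
                                   stimulation_main = it$stimulation_main,
                                   interaction = it$interaction,
                                   interaction_p = it$interaction_p,
                                   slope_unstim = it$slope_unstim,
                                   p_unstim = it$p_unstim,
                                   slope_stim = it$slope_stim,
                                   p_stim = it$p_stim,
                                   stringsAsFactors = FALSE)
      }
    }
    res <- do.call(rbind, rows)
    sel <- fdr_select(stats::setNames(res$beta_p, res$gene),
                      config$thresholds$fdr_level %||% 0.05)
    res$fdr_significant <- res$gene %in% sel$selected
    utils::write.table(res, out("eqtl_results.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    record("eqtl_results.tsv")
    if (length(inter)) {
      utils::write.table(do.call(rbind, inter), out("eqtl_interaction.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      record("eqtl_interaction.tsv")
    }
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  .pipe_log("pipeline complete", logfile, verbose)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the generator and threshold field names. Nested
#' generator tables (`allele_pool`, `haplotype_table`, `markers`,
#' `marker_alleles`, `eqtl_specs`) are converted from plain YAML
#' structures to the shapes [generator_config()] expects.
#'
#' @param path YAML file path.
#' @return A configuration list for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen <- y$generator
  if (!is.null(gen$allele_pool))
    gen$allele_pool <- lapply(gen$allele_pool, function(p) unlist(p))
  if (!is.null(gen$haplotype_table))
    gen$haplotype_table <- as.data.frame(lapply(gen$haplotype_table, unlist),
                                         stringsAsFactors = FALSE)
  if (!is.null(gen$markers))
    gen$markers <- as.data.frame(lapply(gen$markers, unlist),
                                 stringsAsFactors = FALSE)
  if (!is.null(gen$marker_alleles))
    gen$marker_alleles <- do.call(rbind, gen$marker_alleles)
  if (!is.null(gen$eqtl_specs))
    gen$eqtl_specs <- as.data.frame(lapply(gen$eqtl_specs, unlist),
                                    stringsAsFactors = FALSE)
  for (nm in c("mu_locus", "stim_logfold"))
    if (!is.null(gen[[nm]])) gen[[nm]] <- unlist(gen[[nm]])
  y$generator <- do.call(generator_config, gen)
  if (!is.null(y$thresholds$qc)) y$thresholds$qc <- do.call(qc_thresholds, y$thresholds$qc)
  if (!is.null(y$tss)) y$tss <- as.data.frame(lapply(y$tss, unlist),
                                              stringsAsFactors = FALSE)
  if (is.null(y$seed)) stop("config must carry a seed")
  y
}
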