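#' Genotype matrix container
#'
#' Samples-by-variants dosage matrix with 1-based variant coordinates.
#' Dosages are alternate-allele counts in `{0, 1, 2}` or `NA` (missing).
#' Variant ids are canonicalized to `"chrom:pos:ref:alt"`.
#'
#' @param samples Character vector of sample ids.
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   and optionally `id` (filled in canonically when absent).
#' @param dosages Numeric matrix, `length(samples)` rows by
#'   `nrow(variants)` columns.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(samples, variants, dosages) {
  stopifnot(is.character(samples), is.data.frame(variants))
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
    stop("variants needs columns chrom, pos, ref, alt")
  if (is.null(variants$id))
    variants$id <- variant_id(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  for (chr in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == chr]
    if (is.unsorted(p)) stop("variant positions must be sorted within chromosome")
  }
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != length(samples) || ncol(dosages) != nrow(variants))
    stop("dosage dimensions do not match samples x variants")
  ok <- dosages %in% c(0, 1, 2) | is.na(dosages)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(samples, variants$id)
  rownames(variants) <- NULL
  structure(list(samples = samples, variants = variants, dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d variants (%s)\n",
              length(x$samples), nrow(x$variants),
              paste(unique(x$variants$chrom), collapse = ", ")))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.3f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$variants))

.expr_cols <- c("sample_id", "locus", "allele", "copy", "condition", "tpm")

#' Validate an allelic expression table
#'
#' Checks the invariants of the allelic expression format: positive tpm,
#' exactly two allele records per (sample, locus, condition), and allele
#' names identical across conditions within a sample and locus.
#' Violations are reported together with their row numbers.
#'
#' @param expr Data frame of expression records.
#' @return `expr`, invisibly, if valid; otherwise an error listing
#'   offending rows.
#' @export
validate_expression <- function(expr) {
  missing_cols <- setdiff(.expr_cols, names(expr))
  if (length(missing_cols))
    stop("missing expression columns: ", paste(missing_cols, collapse = ", "))
  problems <- character()
  bad_tpm <- which(!is.finite(expr$tpm) | expr$tpm <= 0)
  if (length(bad_tpm))
    problems <- c(problems, paste0("non-positive tpm at rows: ",
                                   paste(bad_tpm, collapse = ", ")))
  bad_copy <- which(!expr$copy %in% c(1L, 2L))
  if (length(bad_copy))
    problems <- c(problems, paste0("allele copy not in {1,2} at rows: ",
                                   paste(bad_copy, collapse = ", ")))
  bad_cond <- which(!expr$condition %in% c("fresh", "unstim", "stim"))
  if (length(bad_cond))
    problems <- c(problems, paste0("unknown condition at rows: ",
                                   paste(bad_cond, collapse = ", ")))
  key <- paste(expr$sample_id, expr$locus, expr$condition, sep = "\r")
  cnt <- table(key)
  bad_key <- names(cnt)[cnt != 2L]
  if (length(bad_key)) {
    rows <- which(key %in% bad_key)
    problems <- c(problems,
                  paste0("not exactly 2 allele records per (sample, locus, condition) at rows: ",
                         paste(rows, collapse = ", ")))
  }
  sl <- paste(expr$sample_id, expr$locus, sep = "\r")
  for (g in split(seq_len(nrow(expr)), sl)) {
    sets <- split(expr$allele[g], expr$condition[g])
    sets <- lapply(sets, sort)
    if (length(unique(sets)) > 1)
      problems <- c(problems,
                    paste0("allele names differ across conditions at rows: ",
                           paste(g, collapse = ", ")))
  }
  if (length(problems))
    stop("invalid expression table:\n  ", paste(problems, collapse = "\n  "))
  invisible(expr)
}

#' Read an allelic expression table (TSV)
#'
#' Expects a tab-separated file with header `sample_id`, `locus`,
#' `allele`, `copy`, `condition`, `tpm`. Gzipped files are accepted.
#' Invalid rows are rejected with row numbers rather than coerced.
#'
#' @param path File path.
#' @return Validated expression data frame.
#' @export
read_expression_table <- function(path) {
  expr <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_expression(expr)
  expr
}

#' Write an allelic expression table (TSV)
#'
#' @param expr Expression data frame.
#' @param path Output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expr, path) {
  validate_expression(expr)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(expr[.expr_cols], con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Reads a VCF v4.2 file (plain or gzipped) carrying unphased GT calls
#' and returns alternate-allele dosages. Multi-allelic records and
#' phased or malformed GT fields are rejected; `./.` becomes missing.
#'
#' @param path VCF file path.
#' @return A [genotype_matrix()].
#' @export
read_vcf_minimal <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF contains no variant records")
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multi-allelic records not supported (rows: ",
         paste(which(multi), collapse = ", "), ")")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt[is.na(gt)] <- "./."   # vcfR reads missing GT as NA
  known <- c("0/0", "0/1", "1/0", "1/1", "./.")
  bad <- !(gt %in% known)
  if (any(bad)) {
    off <- unique(gt[bad])
    stop("malformed or unsupported GT values: ", paste(off, collapse = ", "))
  }
  dos <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  map <- c("0/0" = 0, "0/1" = 1, "1/0" = 1, "1/1" = 2, "./." = NA_real_)
  dos[] <- t(matrix(map[gt], nrow = nrow(gt)))
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(colnames(gt), variants, dos)
}

#' Write genotypes as a minimal VCF v4.2
#'
#' Emits unphased GT-only records, 1-based positions, plain text (or
#' gzip with a `.gz` suffix).
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  gt_str <- c("0/0", "0/1", "1/1")
  enc <- function(d) ifelse(is.na(d), "./.", gt_str[d + 1L])
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", gm$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(gm$variants)), function(i) {
    v <- gm$variants[i, ]
    paste(c(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
            enc(gm$dosages[, i])), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read a TSS table
#'
#' Tab-separated file with header `gene`, `chrom`, `tss`, `strand`
#' (1-based TSS positions). One entry per gene.
#'
#' @param path File path.
#' @return Data frame keyed by gene.
#' @export
read_tss_table <- function(path) {
  tss <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "tss", "strand")
  missing_cols <- setdiff(need, names(tss))
  if (length(missing_cols))
    stop("missing TSS columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tss$gene))
    stop("duplicate gene entries in TSS table")
  if (!is.numeric(tss$tss) || any(tss$tss < 1))
    stop("tss must be positive 1-based positions")
  tss$chrom <- as.character(tss$chrom)
  tss$gene <- as.character(tss$gene)
  tss
}

#' Write a TSS table
#'
#' @param tss Data frame with columns `gene`, `chrom`, `tss`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_table <- function(tss, path) {
  utils::write.table(tss[c("gene", "chrom", "tss", "strand")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
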