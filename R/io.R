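#' Read a genotype matrix from VCF or TSV
#'
#' VCF input (via \pkg{vcfR}) keeps biallelic SNP records only; multiallelic
#' or non-SNP records and half-calls are skipped or set missing, with counts
#' reported in the `skipped` attribute. TSV input expects rows = SNPs with
#' columns `id`, `chrom`, `pos`, `minor`, `major` followed by one column per
#' subject holding 0/1/2 or `NA`. Either way the returned matrix is coded on
#' the in-sample minor allele ([genotype_matrix()] re-orients and logs swaps).
#'
#' @param path Input file.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @param subjects Optional subject table (`subject_id`, `sex`) to attach;
#'   defaults to all-female placeholders, which is only adequate when no
#'   X-chromosome markers are analysed.
#' @return A [genotype_matrix()], with attribute `skipped` (named counts).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv"),
                           subjects = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") .read_genotypes_vcf(path, subjects)
  else .read_genotypes_tsv(path, subjects)
}

.default_subjects <- function(ids) {
  data.frame(subject_id = ids, sex = "F", stringsAsFactors = FALSE)
}

.read_genotypes_vcf <- function(path, subjects = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  ref <- fx[, "REF"]; alt <- fx[, "ALT"]
  is_snp <- nchar(ref) == 1 & nchar(alt) == 1 & !grepl(",", alt)
  n_multi <- sum(grepl(",", alt))
  n_nonsnp <- sum(!is_snp) - n_multi
  if (anyDuplicated(fx[is_snp, "ID"]))
    stop("read_genotypes: duplicate SNP id in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  # diploid GT lookup; half-calls and anything non-0/1 become missing
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  calls <- matrix(lut[gsub("|", "/", gt, fixed = TRUE)],
                  nrow = nrow(gt), ncol = ncol(gt))
  snps <- data.frame(id = fx[is_snp, "ID"], chrom = fx[is_snp, "CHROM"],
                     pos = as.numeric(fx[is_snp, "POS"]),
                     minor = alt[is_snp], major = ref[is_snp],
                     stringsAsFactors = FALSE)
  if (is.null(subjects)) subjects <- .default_subjects(colnames(gt))
  g <- genotype_matrix(t(calls), snps, subjects)
  attr(g, "skipped") <- c(multiallelic = n_multi, non_snp = n_nonsnp)
  g
}


.read_genotypes_tsv <- function(path, subjects = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- c("id", "chrom", "pos", "minor", "major")
  if (!all(meta_cols %in% names(d)))
    stop("read_genotypes: TSV must carry columns ", paste(meta_cols, collapse = ", "))
  if (anyDuplicated(d$id)) stop("read_genotypes: duplicate SNP id in ", path)
  subj_cols <- setdiff(names(d), meta_cols)
  calls <- t(as.matrix(d[, subj_cols, drop = FALSE]))
  if (is.null(subjects)) subjects <- .default_subjects(subj_cols)
  snps <- d[, meta_cols]
  snps$chrom <- as.character(snps$chrom)
  g <- genotype_matrix(calls, snps, subjects)
  attr(g, "skipped") <- c(multiallelic = 0L, non_snp = 0L)
  g
}

#' Write a genotype matrix
#'
#' `write_genotypes_tsv` writes the SNP-major TSV matrix format read back by
#' [read_genotypes()]; `write_genotypes_vcf` writes a minimal plain-text
#' VCFv4.2 with GT-only genotype fields (missing as `./.`). In the VCF, REF
#' is the major and ALT the minor allele, so alt-allele dosage equals the
#' minor-allele count.
#'
#' @param geno A [genotype_matrix()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  d <- cbind(geno$snps, as.data.frame(t(geno$calls)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=mecgwas",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$subjects$subject_id),
                     collapse = "\t")), con)
  gt_map <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno$calls))) {
    g <- geno$calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1])
    writeLines(paste(c(geno$snps$chrom[j], geno$snps$pos[j], geno$snps$id[j],
                       geno$snps$major[j], geno$snps$minor[j], ".", "PASS",
                       ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read / write dosing histories as CSV
#'
#' Long format with columns `subject_id`, `time_min`, `dose_ug`, `kind`
#' (`initial_bolus` / `pca_demand`); times in minutes since end of surgery.
#'
#' @param path CSV file.
#' @param observation_end_min Horizon attached to each parsed history.
#' @param capacity_ug Reservoir capacity used for validation.
#' @return `read_dosing_csv`: named list of [dosing_history()] objects.
#' @export
read_dosing_csv <- function(path, observation_end_min = 1440,
                            capacity_ug = 1000) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "time_min", "dose_ug", "kind")
  if (!all(need %in% names(d)))
    stop("read_dosing_csv: header must carry ", paste(need, collapse = ", "))
  out <- lapply(split(d, d$subject_id), function(s) {
    dosing_history(s$subject_id[1], s$time_min, s$dose_ug, s$kind,
                   observation_end_min = observation_end_min,
                   capacity_ug = capacity_ug)
  })
  out[unique(d$subject_id)]
}

#' @rdname read_dosing_csv
#' @param histories Named list of [dosing_history()] objects.
#' @export
write_dosing_csv <- function(histories, path) {
  rows <- lapply(histories, function(h) {
    cbind(subject_id = h$subject_id, h$events)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the covariate table as CSV
#' @param path CSV file keyed by `subject_id`.
#' @return `read_covariates_csv`: a covariate table data frame.
#' @export
read_covariates_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(d))
    stop("read_covariates_csv: header must carry subject_id")
  class(d) <- c("covariate_table", "data.frame")
  d
}

#' @rdname read_covariates_csv
#' @param covars Covariate table.
#' @export
write_covariates_csv <- function(covars, path) {
  utils::write.csv(covars, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a phenotype table (missing window means as empty fields)
#' @param pheno Phenotype table from [mec_phenotype_table()].
#' @param path CSV file.
#' @export
write_phenotypes_csv <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Fills defaults for every threshold of the staged design: stage alpha 0.05,
#' pruning r-squared 0.8, q-value cutoff 0.05, three stages.
#'
#' @param path YAML file.
#' @return A list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(pk_block = "shafer_fentanyl",
                   phenotype = list(site = "effect", window_h = 12),
                   stages = 3, alpha = 0.05, prune_r2 = 0.8,
                   q_threshold = 0.05, models = c("additive", "dominant", "recessive"),
                   covariate_policy = "screen", seed = 1)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = c("pipeline_config", "list"))
}
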