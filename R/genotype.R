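#' Genotype matrix container
#'
#' Subjects-by-SNPs matrix of minor-allele counts (0/1/2, `NA` missing) with
#' SNP metadata and a per-subject sex flag (needed for the X-chromosome rule
#' of the association stage). On construction, any SNP whose coded allele has
#' in-sample frequency above 0.5 is re-oriented so the coded allele is the
#' minor allele; swaps are recorded in the `swapped` attribute.
#'
#' @param calls Integer matrix, subjects in rows, SNPs in columns, values in
#'   `{0, 1, 2, NA}`.
#' @param snps Data frame with columns `id`, `chrom` (`"1"`..`"22"`, `"X"`),
#'   `pos` (bp), `minor`, `major`; one row per column of `calls`.
#' @param subjects Data frame with columns `subject_id` and `sex`
#'   (`"M"`/`"F"`); one row per row of `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, snps, subjects) {
  calls <- as.matrix(calls)
  stopifnot(nrow(snps) == ncol(calls), nrow(subjects) == nrow(calls),
            all(c("id", "chrom", "pos", "minor", "major") %in% names(snps)),
            all(c("subject_id", "sex") %in% names(subjects)))
  if (anyDuplicated(snps$id)) stop("genotype_matrix: duplicate SNP ids")
  ok <- calls %in% c(0L, 1L, 2L) | is.na(calls)
  if (!all(ok)) stop("genotype_matrix: calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"
  maf <- colMeans(calls, na.rm = TRUE) / 2
  swap <- !is.na(maf) & maf > 0.5
  if (any(swap)) {
    calls[, swap] <- 2L - calls[, swap]
    tmp <- snps$minor[swap]
    snps$minor[swap] <- snps$major[swap]
    snps$major[swap] <- tmp
  }
  dimnames(calls) <- list(subjects$subject_id, snps$id)
  structure(list(calls = calls, snps = snps, subjects = subjects,
                 swapped = snps$id[swap]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d subjects x %d SNPs (%d re-oriented to minor allele)\n",
              nrow(x$calls), ncol(x$calls), length(x$swapped)))
  invisible(x)
}

#' Minor-allele frequencies of a genotype matrix
#' @param geno A [genotype_matrix()].
#' @return Named numeric vector of in-sample minor allele frequencies.
#' @export
minor_allele_freq <- function(geno) colMeans(geno$calls, na.rm = TRUE) / 2

#' Code genotypes under a genetic model
#'
#' Additive coding is the minor-allele count itself; dominant is the carrier
#' indicator (any minor allele); recessive is the homozygous-minor indicator.
#' Missing calls propagate as `NA`.
#'
#' @param count Minor-allele count(s) in `{0, 1, 2, NA}`.
#' @param model `"additive"`, `"dominant"` or `"recessive"`.
#' @return Numeric code(s).
#' @examples
#' encode_genotype(c(0, 1, 2), "dominant")   # 0 1 1
#' encode_genotype(c(0, 1, 2), "recessive")  # 0 0 1
#' @export
encode_genotype <- function(count, model = c("additive", "dominant", "recessive")) {
  model <- match.arg(model)
  bad <- !is.na(count) & !(count %in% c(0, 1, 2))
  if (any(bad)) stop("encode_genotype: counts must be 0, 1, 2 or NA")
  switch(model,
         additive  = as.numeric(count),
         dominant  = as.numeric(count >= 1),
         recessive = as.numeric(count == 2))
}
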