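#' Two-locus linkage disequilibrium from unphased genotypes (EM)
#'
#' Estimates the four haplotype frequencies of a biallelic SNP pair from
#' unphased diplotypes by expectation-maximization: all genotype
#' combinations except the double heterozygote resolve to known haplotype
#' counts, and double heterozygotes are split between the two possible phase
#' configurations in proportion to their current frequency products. From the
#' converged frequencies, `D = p_AB - p_A p_B`, `D' = |D| / D_max` and
#' `r^2 = D^2 / (p_A p_a p_B p_b)`.
#'
#' @param g1,g2 Minor-allele count vectors (0/1/2, `NA` allowed) for the two
#'   SNPs over the same subjects.
#' @param max_iter,tol EM iteration cap and convergence tolerance on
#'   haplotype frequencies.
#' @return A list of class `ld_result`: `hap_freq` (named `AB`, `Ab`, `aB`,
#'   `ab`, where `A`/`B` are the minor alleles), `D`, `Dprime`, `r2`,
#'   `n_used`, `loglik` (trajectory), and `defined` (`FALSE` when either SNP
#'   is monomorphic among complete pairs).
#' @export
ld_em <- function(g1, g2, max_iter = 200, tol = 1e-10) {
  stopifnot(length(g1) == length(g2))
  cc <- !is.na(g1) & !is.na(g2)
  g1 <- g1[cc]; g2 <- g2[cc]
  n <- length(g1)
  undefined <- structure(list(hap_freq = rep(NA_real_, 4), D = NA_real_,
                              Dprime = NA_real_, r2 = NA_real_, n_used = n,
                              loglik = numeric(), defined = FALSE),
                         class = "ld_result")
  if (n < 2) return(undefined)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) return(undefined)
  # 3x3 table of genotype pairs, counts of minor alleles at locus 1 (rows)
  # and locus 2 (cols)
  tab <- matrix(0, 3, 3)
  for (i in seq_len(n)) tab[g1[i] + 1, g2[i] + 1] <- tab[g1[i] + 1, g2[i] + 1] + 1
  # haplotypes: 1=AB (minor/minor), 2=Ab, 3=aB, 4=ab
  # known haplotype contributions from the eight unambiguous cells
  base <- c(
    AB = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3],
    Ab = 2 * tab[3, 1] + tab[3, 2] + tab[2, 1],
    aB = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
    ab = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1])
  ndh <- tab[2, 2]  # double heterozygotes: AB/ab or Ab/aB
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  f <- pmax(f, 1e-12); f <- f / sum(f)
  ll <- numeric()
  for (it in seq_len(max_iter)) {
    w_cis <- f[1] * f[4]
    w_trans <- f[2] * f[3]
    phi <- if (w_cis + w_trans > 0) w_cis / (w_cis + w_trans) else 0.5
    cnt <- base + ndh * c(phi, 1 - phi, 1 - phi, phi)
    fn <- cnt / (2 * n)
    ll <- c(ll, .ld_loglik(fn, base, ndh))
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  D <- unname(f[1]) - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(
    hap_freq = stats::setNames(f, c("AB", "Ab", "aB", "ab")),
    D = D,
    Dprime = if (dmax > 0) abs(D) / dmax else NA_real_,
    r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
    n_used = n, loglik = ll, defined = TRUE),
    class = "ld_result")
}

.ld_loglik <- function(f, base, ndh) {
  f <- pmax(f, 1e-300)
  sum(base * log(f)) + ndh * log(2 * (f[1] * f[4] + f[2] * f[3]))
}

#' Pairwise r-squared between SNP columns of a genotype matrix
#'
#' @param geno A [genotype_matrix()].
#' @param ids SNP ids to include (default all).
#' @return Symmetric matrix of EM-based `r^2` values (`NA` where undefined).
#' @export
ld_r2_matrix <- function(geno, ids = geno$snps$id) {
  j <- match(ids, geno$snps$id)
  k <- length(j)
  out <- matrix(NA_real_, k, k, dimnames = list(ids, ids))
  diag(out) <- 1
  if (k > 1) for (a in seq_len(k - 1)) for (b in (a + 1):k) {
    r <- ld_em(geno$calls[, j[a]], geno$calls[, j[b]])
    out[a, b] <- out[b, a] <- r$r2
  }
  out
}

#' Greedy LD-based pruning of association survivors
#'
#' Sorts SNPs by combined p-value ascending (ties broken by position then id)
#' and keeps a SNP if and only if its EM `r^2` with every already-kept SNP is
#' below the threshold; a dropped SNP records the index SNP that removed it.
#'
#' @param records Data frame with columns `snp`, `p`, and (for tie-breaks)
#'   optionally `chrom`/`pos`.
#' @param geno A [genotype_matrix()] providing the calls for `r^2`.
#' @param r2_threshold Pruning threshold, default 0.8.
#' @return `records` with a `pruned_by` column (`NA` for kept SNPs), original
#'   row order preserved.
#' @export
ld_prune <- function(records, geno, r2_threshold = 0.8) {
  stopifnot(all(c("snp", "p") %in% names(records)))
  records$pruned_by <- NA_character_
  if (!nrow(records)) return(records)
  pos <- if ("pos" %in% names(records)) records$pos else rep(0, nrow(records))
  ord <- order(records$p, pos, records$snp)
  kept <- character()
  for (i in ord) {
    jx <- match(records$snp[i], geno$snps$id)
    removed_by <- NA_character_
    for (kid in kept) {
      r <- ld_em(geno$calls[, jx], geno$calls[, match(kid, geno$snps$id)])
      if (r$defined && !is.na(r$r2) && r$r2 >= r2_threshold) {
        removed_by <- kid
        break
      }
    }
    if (is.na(removed_by)) kept <- c(kept, records$snp[i])
    records$pruned_by[i] <- removed_by
  }
  records
}
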