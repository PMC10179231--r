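#' Hardy-Weinberg chi-square goodness-of-fit test
#'
#' One-degree-of-freedom Pearson test of observed genotype counts against the
#' Hardy-Weinberg expectations `n p^2`, `2 n p q`, `n q^2` computed from the
#' sample allele frequency.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote).
#' @return A list of class `hwe_result`: `counts`, `expected`, `chi2`,
#'   `df` (1), `p_chi2`. A monomorphic sample gives `chi2 = 0` by convention.
#' @examples
#' hwe_chi2(171, 137, 41)  # chi2 = 2.7283, p = 0.0986
#' @export
hwe_chi2 <- function(n_AA, n_Aa, n_aa) {
  obs <- c(AA = n_AA, Aa = n_Aa, aa = n_aa)
  if (any(obs < 0) || sum(obs) == 0) stop("hwe_chi2: counts must be >= 0 with positive total")
  n <- sum(obs)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p %in% c(0, 1)) {
    return(structure(list(counts = obs, expected = obs, chi2 = 0, df = 1,
                          p_chi2 = 1), class = "hwe_result"))
  }
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((obs - e)^2 / e)
  structure(list(counts = obs, expected = stats::setNames(e, names(obs)),
                 chi2 = chi2, df = 1,
                 p_chi2 = stats::pchisq(chi2, 1, lower.tail = FALSE)),
            class = "hwe_result")
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test: given the observed allele counts, the p-value is
#' the sum of the conditional probabilities of all heterozygote counts whose
#' probability does not exceed that of the observed count (the standard
#' non-mid-p formulation). Probabilities follow the conditional distribution
#' `P(n_Aa | n, n_A) = n! / (n_AA! n_Aa! n_aa!) * 2^n_Aa * n_A! n_a! / (2n)!`,
#' evaluated by recurrence for numerical stability.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Exact p-value in `[0, 1]`.
#' @examples
#' hwe_exact(171, 137, 41)
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("hwe_exact: counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) return(1)
  n_minor <- 2 * n_aa + n_Aa  # rare-allele copies (orientation-free below)
  if (n_minor > n) n_minor <- 2 * n - n_minor
  # feasible heterozygote counts share the parity of the rare allele count
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  if (!length(hets)) return(1)
  # unnormalized probabilities by recurrence:
  # P(h+2)/P(h) = 4 * n_AA(h) * n_aa(h) / ((h+2)(h+1))
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1]
    naa <- (n_minor - h) / 2
    nAA <- n - naa - h
    logp[i] <- logp[i - 1] + log(4 * nAA * naa) - log((h + 2) * (h + 1))
  }
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  i_obs <- match(n_Aa, hets)
  if (is.na(i_obs)) stop("hwe_exact: inconsistent genotype counts")
  sum(pr[pr <= pr[i_obs] * (1 + 1e-12)])
}

#' Hardy-Weinberg tests for every SNP of a genotype matrix
#'
#' @param geno A [genotype_matrix()].
#' @return Data frame with per-SNP genotype counts, `chi2`, `p_chi2` and
#'   `p_exact`.
#' @export
hwe_table <- function(geno) {
  res <- lapply(seq_len(ncol(geno$calls)), function(j) {
    g <- geno$calls[, j]
    n0 <- sum(g == 0, na.rm = TRUE)
    n1 <- sum(g == 1, na.rm = TRUE)
    n2 <- sum(g == 2, na.rm = TRUE)
    h <- hwe_chi2(n0, n1, n2)
    data.frame(snp = geno$snps$id[j], n_AA = n0, n_Aa = n1, n_aa = n2,
               chi2 = h$chi2, p_chi2 = h$p_chi2,
               p_exact = hwe_exact(n0, n1, n2), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
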