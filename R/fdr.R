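#' Benjamini-Hochberg false-discovery-rate q-values
#'
#' Step-up BH q-values (monotone-enforced). By default the number of tests
#' charged is `length(pvalues)` (plain `stats::p.adjust(method = "BH")`).
#' When the supplied p-values are a pre-selected subset of a larger family —
#' the staged design computes combined p-values only for the markers that
#' survive selection, while the false-discovery correction must still pay
#' for every marker tested in stage 1 — pass the family size as `m`:
#' q-values are then `min_(j >= i) p_(j) * m / j` over the supplied values.
#' With `strata` given, q-values are computed within each stratum separately
#' (a stratified-FDR variant); the default is a single stratum.
#'
#' @param pvalues Numeric p-values in `[0, 1]`.
#' @param strata Optional factor of the same length; q-values computed within
#'   levels.
#' @param m Total number of tests to charge (default `length(pvalues)`;
#'   per-stratum lengths when `strata` is given).
#' @return q-values, same length and order as `pvalues`.
#' @examples
#' fdr_qvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' fdr_qvalues(c(1e-7, 0.002), m = 5e5)    # subset of a 500k-marker family
#' @export
fdr_qvalues <- function(pvalues, strata = NULL, m = NULL) {
  if (!length(pvalues)) return(numeric())
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("fdr_qvalues: p-values must lie in [0, 1]")
  if (!is.null(strata)) {
    stopifnot(length(strata) == length(pvalues))
    q <- rep(NA_real_, length(pvalues))
    for (lev in unique(strata)) {
      i <- which(strata == lev)
      q[i] <- fdr_qvalues(pvalues[i], m = m)
    }
    return(q)
  }
  n <- length(pvalues)
  if (is.null(m)) m <- n
  if (m < n) stop("fdr_qvalues: m must be at least length(pvalues)")
  if (m == n) return(stats::p.adjust(pvalues, method = "BH"))
  o <- order(pvalues)
  q_sorted <- pvalues[o] * m / seq_len(n)
  q_sorted <- pmin(1, rev(cummin(rev(q_sorted))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

#' Expected-versus-observed quantiles for a QQ p-value plot
#'
#' Pairs the sorted observed p-values (ascending) with uniform-null expected
#' quantiles `i / (m + 1)`, both on the `-log10` scale. Zero p-values are
#' clipped at a configurable floor with a warning.
#'
#' @param pvalues Observed p-values in `(0, 1]` (zeros clipped).
#' @param floor Clipping floor for zero p-values.
#' @return Data frame with columns `expected` and `observed`
#'   (`-log10` scale), ordered by ascending p.
#' @export
qq_data <- function(pvalues, floor = 1e-300) {
  pvalues <- pvalues[!is.na(pvalues)]
  if (any(pvalues < 0 | pvalues > 1))
    stop("qq_data: p-values must lie in [0, 1]")
  if (any(pvalues == 0)) {
    warning(sprintf("qq_data: %d zero p-value(s) clipped at %g",
                    sum(pvalues == 0), floor))
    pvalues[pvalues == 0] <- floor
  }
  m <- length(pvalues)
  if (!m) return(data.frame(expected = numeric(), observed = numeric()))
  p_sorted <- sort(pvalues)
  data.frame(expected = -log10(seq_len(m) / (m + 1)),
             observed = -log10(p_sorted))
}
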