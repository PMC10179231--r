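#' Spearman rank correlation with a p-value
#'
#' Rank correlation with average ranks for ties. The two-sided p-value uses
#' the t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees
#' of freedom; for `n <= exact_n` (default 9) the exact permutation null is
#' enumerated instead (valid with ties).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact_n Largest n at which the full permutation null is enumerated.
#' @return A list of class `screen_result`: `statistic` (`"spearman_rho"`),
#'   `value`, `p`, `n`, `method`; `defined = FALSE` with `NA`s when either
#'   vector is constant.
#' @export
spearman_rho <- function(x, y, exact_n = 9) {
  stopifnot(length(x) == length(y))
  cc <- stats::complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  n <- length(x)
  if (n < 3) stop("spearman_rho: need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(structure(list(statistic = "spearman_rho", value = NA_real_,
                          p = NA_real_, n = n, method = "undefined",
                          defined = FALSE), class = "screen_result"))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    perms <- .permutations(n)
    # cor is affine in S = sum(rx * permuted ry) for fixed rank multisets
    S_all <- matrix(ry[perms], nrow(perms), n) %*% rx
    stats_all <- (S_all - n * mean(rx) * mean(ry)) /
      ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(stats_all) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else if (abs(rho) >= 1) {
    p <- 0; method <- "t_approx"
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
    method <- "t_approx"
  }
  structure(list(statistic = "spearman_rho", value = rho, p = p, n = n,
                 method = method, defined = TRUE), class = "screen_result")
}

# all permutations of 1..n as an (n!) x n matrix
.permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- .permutations(n - 1)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }
  do.call(rbind, out)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. `U` counts the pairs where a group-A value
#' exceeds a group-B value (ties counted one half). For total sample size at
#' most `exact_n` (default 12) the p-value sums the exact null over all
#' label assignments (valid with ties); above that a tie-corrected normal
#' approximation with continuity correction is used.
#'
#' @param groupA,groupB Numeric vectors, both non-empty.
#' @param exact_n Largest total n for exact enumeration.
#' @return A list of class `screen_result`: `statistic` (`"mannwhitney_U"`),
#'   `value` (U for group A), `p`, `n`, `method`.
#' @export
mann_whitney <- function(groupA, groupB, exact_n = 12) {
  groupA <- groupA[!is.na(groupA)]; groupB <- groupB[!is.na(groupB)]
  nA <- length(groupA); nB <- length(groupB)
  if (!nA || !nB) stop("mann_whitney: both groups must be non-empty")
  pooled <- c(groupA, groupB)
  r <- rank(pooled)
  U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  n <- nA + nB
  mu <- nA * nB / 2
  if (n <= exact_n) {
    idx <- utils::combn(n, nA)
    Uall <- apply(idx, 2, function(ia) sum(r[ia]) - nA * (nA + 1) / 2)
    p <- mean(abs(Uall - mu) >= abs(U - mu) - 1e-12)
    method <- "exact_enumeration"
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nA * nB / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approx"
  }
  structure(list(statistic = "mannwhitney_U", value = U, p = p, n = n,
                 method = method, defined = TRUE), class = "screen_result")
}

#' Screen clinical variables against a log-MEC phenotype
#'
#' One joint ordinary-least-squares regression of the phenotype on all
#' candidate clinical variables; per-variable coefficient, two-sided t-test
#' p-value, and a flag marking variables passing `p < alpha` as covariates
#' for the association stage. Exactly collinear variables are dropped with a
#' note.
#'
#' @param pheno Numeric phenotype vector (log-MEC).
#' @param clinical Data frame or matrix of clinical variables (numeric).
#' @param alpha Significance threshold for flagging.
#' @return Data frame of class `covariate_screen`: `variable`, `beta`, `se`,
#'   `p`, `selected`, `dropped_collinear`.
#' @export
covariate_screen <- function(pheno, clinical, alpha = 0.05) {
  X <- as.matrix(clinical)
  if (is.null(colnames(X))) colnames(X) <- paste0("v", seq_len(ncol(X)))
  cc <- stats::complete.cases(X, pheno)
  if (sum(cc) < ncol(X) + 2) stop("covariate_screen: too few complete cases")
  Xc <- cbind(`(Intercept)` = 1, X[cc, , drop = FALSE])
  yc <- pheno[cc]
  qrX <- qr(Xc)
  dropped <- character()
  if (qrX$rank < ncol(Xc)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(colnames(Xc), colnames(Xc)[keep])
    dropped <- setdiff(dropped, "(Intercept)")
    message("covariate_screen: dropping collinear variable(s): ",
            paste(dropped, collapse = ", "))
    Xc <- Xc[, sort(keep), drop = FALSE]
  }
  fit <- stats::lm.fit(Xc, yc)
  df <- length(yc) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df
  R <- fit$qr$qr[seq_len(fit$rank), , drop = FALSE]
  XtXinv <- chol2inv(R)
  se_all <- sqrt(sigma2 * diag(XtXinv))[order(fit$qr$pivot)]
  beta_all <- fit$coefficients
  vars <- setdiff(colnames(Xc), "(Intercept)")
  beta <- beta_all[vars]
  se <- se_all[match(vars, colnames(Xc))]
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df, lower.tail = FALSE)
  out <- data.frame(variable = c(vars, dropped),
                    beta = c(unname(beta), rep(NA_real_, length(dropped))),
                    se = c(unname(se), rep(NA_real_, length(dropped))),
                    p = c(unname(p), rep(NA_real_, length(dropped))),
                    stringsAsFactors = FALSE)
  out$selected <- !is.na(out$p) & out$p < alpha
  out$dropped_collinear <- out$variable %in% dropped
  class(out) <- c("covariate_screen", "data.frame")
  out
}
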