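#' Per-SNP covariate-adjusted linear regression
#'
#' Ordinary least squares of a (log-transformed) MEC phenotype on an
#' intercept, a coded genotype and optional covariates, over complete cases.
#' The reported effect, standard error and two-sided t-test p-value are for
#' the genotype term.
#'
#' @param pheno Numeric phenotype vector.
#' @param code Coded genotype vector (same length), `NA` allowed.
#' @param covars Optional numeric matrix or data frame of covariates.
#' @return A list of class `snp_fit`: `beta`, `se`, `t_stat`, `p`, `n_used`,
#'   and `flag` (`"ok"`, `"monomorphic"`, `"collinear"`, or `"insufficient_n"`).
#'   A non-`"ok"` flag carries `NA` statistics.
#' @export
snp_regression <- function(pheno, code, covars = NULL) {
  n <- length(pheno)
  stopifnot(length(code) == n)
  X <- cbind(`(Intercept)` = 1, genotype = as.numeric(code))
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    stopifnot(nrow(covars) == n)
    X <- cbind(X, covars)
  }
  cc <- stats::complete.cases(X, pheno)
  bad <- function(flag) structure(list(beta = NA_real_, se = NA_real_,
                                       t_stat = NA_real_, p = NA_real_,
                                       n_used = sum(cc), flag = flag),
                                  class = "snp_fit")
  if (sum(cc) < ncol(X) + 1) return(bad("insufficient_n"))
  Xc <- X[cc, , drop = FALSE]
  yc <- pheno[cc]
  g <- Xc[, 2L]
  if (all(g == g[1L])) return(bad("monomorphic"))
  fit <- stats::lm.fit(Xc, yc)
  if (fit$rank < ncol(Xc)) return(bad("collinear"))
  df <- length(yc) - fit$rank
  sigma2 <- sum(fit$residuals^2) / df
  R <- fit$qr$qr[seq_len(fit$rank), , drop = FALSE]
  XtXinv <- chol2inv(R)
  jp <- match(2L, fit$qr$pivot)  # position of the genotype column after pivoting
  se <- sqrt(sigma2 * XtXinv[jp, jp])
  beta <- unname(fit$coefficients["genotype"])
  tval <- beta / se
  structure(list(beta = beta, se = se, t_stat = tval,
                 p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE),
                 n_used = length(yc), flag = "ok"),
            class = "snp_fit")
}

#' Stage plan for a multi-stage association design
#'
#' Partitions subjects into sequential analysis stages and fixes the design
#' thresholds: the per-stage selection alpha, the LD-pruning r-squared
#' threshold and the FDR q-value cutoff for genome-wide significance.
#'
#' @param subject_ids Ordered subject identifiers to analyse.
#' @param sizes Stage sizes; default three equal stages (e.g. 117/117/117 for
#'   351 subjects). Must sum to the number of subjects.
#' @param alpha Per-stage (and combined-test) selection threshold.
#' @param prune_r2 r-squared threshold for greedy LD pruning.
#' @param q_threshold q-value cutoff for genome-wide significance.
#' @param method `"contiguous"` assigns in input order; `"random"` shuffles
#'   first (seeded).
#' @param seed Seed for `method = "random"`.
#' @return An object of class `stage_plan` with a `stage` assignment per
#'   subject.
#' @export
stage_plan <- function(subject_ids, sizes = NULL, alpha = 0.05,
                       prune_r2 = 0.8, q_threshold = 0.05,
                       method = c("contiguous", "random"), seed = NULL) {
  method <- match.arg(method)
  n <- length(subject_ids)
  if (is.null(sizes)) {
    k <- 3
    sizes <- rep(n %/% k, k)
    if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1
  }
  if (sum(sizes) != n) stop("stage_plan: sizes must sum to the number of subjects")
  if (alpha <= 0 || alpha > 1 || prune_r2 <= 0 || prune_r2 > 1 ||
      q_threshold <= 0 || q_threshold > 1)
    stop("stage_plan: thresholds must lie in (0, 1]")
  ids <- subject_ids
  if (method == "random") {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    ids <- sample(ids)
  }
  stage <- rep(seq_along(sizes), sizes)
  structure(list(subject_id = ids, stage = stage, sizes = sizes,
                 alpha = alpha, prune_r2 = prune_r2,
                 q_threshold = q_threshold),
            class = "stage_plan")
}

#' Pooled combined regression over the first k stages
#'
#' The combined analysis after stage k is a single pooled OLS fit over all
#' subjects of stages 1..k, with the same covariates and no stage indicator
#' (set `stage_effect = TRUE` to add stage fixed effects).
#'
#' @param pheno Named phenotype vector (names are subject ids).
#' @param code Named coded-genotype vector.
#' @param covars Covariate matrix/data frame with rownames = subject ids, or
#'   `NULL`.
#' @param plan A [stage_plan()].
#' @param k Number of leading stages to pool.
#' @param stage_effect Add stage fixed-effect covariates (default off).
#' @return A `snp_fit` (see [snp_regression()]).
#' @export
combine_stages <- function(pheno, code, covars, plan, k,
                           stage_effect = FALSE) {
  ids <- plan$subject_id[plan$stage <= k]
  Xc <- if (is.null(covars)) NULL else covars[match(ids, rownames(covars)), , drop = FALSE]
  if (stage_effect && k > 1) {
    st <- factor(plan$stage[plan$stage <= k])
    dm <- stats::model.matrix(~ st)[, -1, drop = FALSE]
    Xc <- if (is.null(Xc)) dm else cbind(Xc, dm)
  }
  snp_regression(pheno[ids], code[ids], Xc)
}

#' Three-stage genome-wide association scan of an MEC phenotype
#'
#' Implements the sequential selection design: every SNP is tested in stage 1
#' and survives if its stage-1 p-value is below `alpha`; at each later stage
#' k a surviving SNP must show p below `alpha` both in the single analysis of
#' stage k and in the pooled combined analysis of stages 1..k. The SNPs
#' entering the final stage (those selected after the penultimate stage) are
#' greedily LD-pruned on the final combined p-value ([ld_prune()]) and
#' Benjamini-Hochberg q-values are computed over the pruned set
#' ([fdr_qvalues()]); a SNP is flagged genome-wide significant when it also
#' survives the final stage itself and its q is below the plan's threshold.
#' For X-chromosome markers
#' male subjects are excluded from every fit; monomorphic or collinear SNPs
#' are skipped with a flag.
#'
#' @param geno A [genotype_matrix()].
#' @param pheno Named numeric vector of log-MEC values (names = subject ids;
#'   `NA` drops the subject from fits on this phenotype).
#' @param covars Covariate matrix or data frame with rownames = subject ids
#'   (or a covariate table from [gen_covariates()]), or `NULL` for unadjusted
#'   fits.
#' @param plan A [stage_plan()] over the analyzed subjects.
#' @param model Genetic model passed to [encode_genotype()].
#' @param stage_effect Passed to [combine_stages()].
#' @return A data frame of class `assoc_table`, one row per SNP: per-stage
#'   beta/p, combined beta/p after each pooled analysis, `survived_stage`,
#'   `pruned_by` (id of the index SNP that removed it, `NA` if kept or never
#'   a survivor), `q`, `significant`, `flag`.
#' @export
staged_gwas <- function(geno, pheno, covars, plan,
                        model = c("additive", "dominant", "recessive"),
                        stage_effect = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(geno, "genotype_matrix"), inherits(plan, "stage_plan"))
  if (is.null(names(pheno))) stop("staged_gwas: pheno must be named by subject id")
  if (is.data.frame(covars) && "subject_id" %in% names(covars))
    covars <- as_covariate_matrix(covars)
  S <- length(plan$sizes)
  snps <- geno$snps
  m <- nrow(snps)
  sex <- geno$subjects$sex[match(plan$subject_id, geno$subjects$subject_id)]
  is_x <- snps$chrom == "X"

  stage_beta <- matrix(NA_real_, m, S)
  stage_p <- matrix(NA_real_, m, S)
  comb_beta <- matrix(NA_real_, m, S)
  comb_p <- matrix(NA_real_, m, S)
  survived <- integer(m)
  flag <- rep("ok", m)

  fit_set <- function(j, ids) {
    code <- encode_genotype(geno$calls[match(ids, rownames(geno$calls)), j], model)
    Xc <- if (is.null(covars)) NULL else covars[match(ids, rownames(covars)), , drop = FALSE]
    snp_regression(pheno[ids], code, Xc)
  }

  alive <- rep(TRUE, m)
  for (s in seq_len(S)) {
    ids_auto <- plan$subject_id[plan$stage == s]
    ids_fem  <- ids_auto[sex[plan$stage == s] != "M"]
    pool_auto <- plan$subject_id[plan$stage <= s]
    pool_fem  <- pool_auto[sex[plan$stage <= s] != "M"]
    for (j in which(alive)) {
      f <- fit_set(j, if (is_x[j]) ids_fem else ids_auto)
      stage_beta[j, s] <- f$beta
      stage_p[j, s] <- f$p
      if (f$flag != "ok") { flag[j] <- f$flag; alive[j] <- FALSE; next }
      pass <- f$p < plan$alpha
      # the pooled combined statistic is computed for every final-stage
      # entrant (it feeds pruning and FDR), and for earlier stages only when
      # the single-stage filter passes
      if (s > 1 && (pass || s == S)) {
        fc <- fit_set(j, if (is_x[j]) pool_fem else pool_auto)
        comb_beta[j, s] <- fc$beta
        comb_p[j, s] <- fc$p
        pass <- pass && !is.na(fc$p) && fc$p < plan$alpha
      }
      if (pass) survived[j] <- s
      alive[j] <- pass
    }
  }

  res <- data.frame(snp = snps$id, chrom = snps$chrom, pos = snps$pos,
                    model = model, stringsAsFactors = FALSE)
  for (s in seq_len(S)) {
    res[[sprintf("stage%d_beta", s)]] <- stage_beta[, s]
    res[[sprintf("stage%d_p", s)]] <- stage_p[, s]
  }
  if (S > 1) for (s in 2:S) {
    res[[sprintf("combined%d_beta", s)]] <- comb_beta[, s]
    res[[sprintf("combined%d_p", s)]] <- comb_p[, s]
  }
  res$survived_stage <- survived
  res$flag <- flag
  res$pruned_by <- NA_character_
  res$q <- NA_real_
  res$significant <- FALSE

  # FDR stratum: SNPs selected after the penultimate stage (the final-stage
  # entrants), LD-pruned on the final combined p; genome-wide significance
  # additionally requires surviving the final stage itself
  finalp <- if (S > 1) comb_p[, S] else stage_p[, 1]
  entered <- which(survived >= S - 1 & !is.na(finalp))
  if (length(entered)) {
    keep_tab <- ld_prune(
      data.frame(snp = res$snp[entered], p = finalp[entered],
                 chrom = res$chrom[entered], pos = res$pos[entered],
                 stringsAsFactors = FALSE),
      geno, r2_threshold = plan$prune_r2)
    res$pruned_by[match(keep_tab$snp, res$snp)] <- keep_tab$pruned_by
    kept <- keep_tab$snp[is.na(keep_tab$pruned_by)]
    ki <- match(kept, res$snp)
    # the correction charges every marker tested in stage 1, not just the
    # selected candidates whose combined p-values reach the final stage
    m_tested <- sum(!is.na(stage_p[, 1]))
    res$q[ki] <- fdr_qvalues(finalp[ki], m = m_tested)
    res$significant[ki] <- res$q[ki] < plan$q_threshold &
      survived[ki] == S
  }
  class(res) <- c("assoc_table", "data.frame")
  res
}
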