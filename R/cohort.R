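#' Specification of a synthetic postoperative PCA cohort
#'
#' Collects every knob of the generative model: cohort and marker panel
#' sizes, minor-allele-frequency distribution, optional LD blocks, causal
#' SNPs with per-copy effects on the latent log effect-site MEC, covariate
#' effect coefficients, residual noise, and the pump program (demand dose,
#' lockout, hourly cap, reservoir capacity). Defaults mirror the study
#' conditions the pipeline targets: 351 subjects analysed in three stages of
#' 117, a 20 ug demand dose with a 5-min lockout, at most 12 demands per
#' rolling hour, and a 1000 ug reservoir.
#'
#' Covariate effect defaults are the reported clinical regression
#' coefficients for the log MEC phenotype (age 0.004 per year, mean
#' remifentanil infusion rate 0.409 per ug/kg/min, end-of-surgery fentanyl
#' 0.001 per ug, 2-h pain score 0.019 per point). The latent intercept and
#' residual SD are chosen so the latent MEC is centred near 1 ng/mL, which
#' yields 24-h PCA consumption approaching, without systematically
#' exhausting, the reservoir.
#'
#' @param n_subjects Number of subjects.
#' @param n_snps Number of SNPs.
#' @param maf_range MAF drawn uniformly from this interval.
#' @param ld_blocks Optional list of `list(size =, rho =)` blocks (`rho` =
#'   target allele-level correlation); blocks are laid down from the first
#'   SNP onward, remaining SNPs independent.
#' @param causal_snps Data frame with columns `snp_index` and `beta`
#'   (per-copy effect on latent log-MEC), optionally `maf` to pin the causal
#'   SNP's minor-allele frequency; or `NULL`.
#' @param covariate_effects Named coefficients for `age`, `remi_rate`,
#'   `endsurg_fentanyl`, `pain2h` on the latent log-MEC scale.
#' @param intercept Latent log-MEC intercept.
#' @param noise_sd Residual SD of latent log-MEC.
#' @param pca_settings Pump program: `demand_dose_ug`, `lockout_min`,
#'   `max_per_hour`, `capacity_ug`.
#' @param initial_bolus_ug End-of-surgery fentanyl bolus (ug) at t = 0.
#' @param behavior_noise_sd SD of multiplicative lognormal noise on the
#'   per-demand trigger threshold (0 = deterministic trigger).
#' @param observation_end_min Observation horizon (min).
#' @param prop_male Proportion of male subjects.
#' @param seed Integer seed; all generators are pure functions of
#'   (spec, seed).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 351,
                        n_snps = 1000,
                        maf_range = c(0.05, 0.5),
                        ld_blocks = NULL,
                        causal_snps = NULL,
                        covariate_effects = c(age = 0.004, remi_rate = 0.409,
                                              endsurg_fentanyl = 0.001,
                                              pain2h = 0.019),
                        intercept = -0.5,
                        noise_sd = 0.3,
                        pca_settings = list(demand_dose_ug = 20,
                                            lockout_min = 5,
                                            max_per_hour = 12,
                                            capacity_ug = 1000),
                        initial_bolus_ug = 100,
                        behavior_noise_sd = 0,
                        observation_end_min = 1440,
                        prop_male = 0.5,
                        seed = 1) {
  stopifnot(n_subjects >= 1, n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            all(unlist(pca_settings) > 0),
            pca_settings$capacity_ug >= pca_settings$demand_dose_ug,
            initial_bolus_ug > 0, behavior_noise_sd >= 0)
  if (!is.null(causal_snps)) {
    stopifnot(all(c("snp_index", "beta") %in% names(causal_snps)),
              all(causal_snps$snp_index >= 1),
              all(causal_snps$snp_index <= n_snps))
  }
  structure(list(n_subjects = n_subjects, n_snps = n_snps,
                 maf_range = maf_range, ld_blocks = ld_blocks,
                 causal_snps = causal_snps,
                 covariate_effects = covariate_effects,
                 intercept = intercept, noise_sd = noise_sd,
                 pca_settings = pca_settings,
                 initial_bolus_ug = initial_bolus_ug,
                 behavior_noise_sd = behavior_noise_sd,
                 observation_end_min = observation_end_min,
                 prop_male = prop_male, seed = seed),
            class = "cohort_spec")
}

# derive a reproducible sub-seed (< 2^31) for each generator component
.sub_seed <- function(seed, offset) (as.integer(seed) %% 1000000L) * 1000L + offset

# latent Gaussian correlation whose thresholded (at qnorm(p), both margins)
# indicators have Pearson correlation phi_target
.tetrachoric_rho <- function(phi_target, p) {
  stopifnot(phi_target > 0, phi_target < 1)
  t <- stats::qnorm(p)
  phi_of <- function(rho) {
    p11 <- stats::integrate(function(z)
      stats::pnorm((t - rho * z) / sqrt(1 - rho^2)) * stats::dnorm(z),
      -Inf, t, rel.tol = 1e-10)$value
    (p11 - p^2) / (p * (1 - p))
  }
  stats::uniroot(function(r) phi_of(r) - phi_target,
                 lower = phi_target * 0.999, upper = 1 - 1e-7,
                 tol = 1e-9)$root
}

#' Generate Hardy-Weinberg genotypes with optional LD blocks
#'
#' Independent SNPs are drawn as two Bernoulli allele copies at the SNP's
#' MAF (Hardy-Weinberg proportions). Within an LD block, SNPs share one MAF
#' and each of a subject's two haplotypes is an exchangeable correlated
#' multivariate-normal draw thresholded at the MAF quantile; the latent
#' correlation is solved (tetrachoric) so the pairwise allele-level
#' correlation equals the block's `rho`, preserving the marginal MAF while
#' giving within-block genotype `r^2` near `rho^2`.
#'
#' @param spec A [cohort_spec()].
#' @return A [genotype_matrix()]; SNPs named `snp0001`... on chromosomes
#'   cycled over 1..22, positions spaced 1e5 bp.
#' @export
gen_genotypes <- function(spec) {
  set.seed(.sub_seed(spec$seed, 1L))
  n <- spec$n_subjects; m <- spec$n_snps
  maf <- stats::runif(m, spec$maf_range[1], spec$maf_range[2])
  # causal SNPs may pin their MAF (e.g. a planted effect at a known MAF)
  if (!is.null(spec$causal_snps) && "maf" %in% names(spec$causal_snps))
    maf[spec$causal_snps$snp_index] <- spec$causal_snps$maf
  calls <- matrix(0L, n, m)
  block_id <- rep(0L, m)
  nxt <- 1L
  if (!is.null(spec$ld_blocks)) {
    for (b in seq_along(spec$ld_blocks)) {
      bl <- spec$ld_blocks[[b]]
      idx <- seq(nxt, length.out = bl$size)
      stopifnot(max(idx) <= m)
      block_id[idx] <- b
      nxt <- nxt + bl$size
    }
  }
  # independent SNPs: genotype ~ Binomial(2, maf)
  ind <- which(block_id == 0L)
  if (length(ind))
    calls[, ind] <- vapply(ind, function(j) stats::rbinom(n, 2L, maf[j]),
                           integer(n))
  # LD blocks: threshold correlated Gaussian haplotypes. SNPs in a block
  # share one MAF, and the latent correlation is solved (tetrachoric) so the
  # pairwise allele-level correlation equals the requested block rho; the
  # genotype r2 between block members is then ~ rho^2.
  if (!is.null(spec$ld_blocks)) {
    for (b in seq_along(spec$ld_blocks)) {
      bl <- spec$ld_blocks[[b]]
      idx <- which(block_id == b)
      k <- length(idx)
      maf[idx] <- maf[idx[1]]
      rho_lat <- .tetrachoric_rho(bl$rho, maf[idx[1]])
      L <- chol(matrix(rho_lat, k, k) + diag(1 - rho_lat, k))
      thr <- stats::qnorm(maf[idx[1]])
      hap <- function() {
        z <- matrix(stats::rnorm(n * k), n, k) %*% L
        (z < thr) + 0L
      }
      calls[, idx] <- hap() + hap()
    }
  }
  chrom <- as.character(rep_len(1:22, m))
  snps <- data.frame(id = sprintf("snp%04d", seq_len(m)), chrom = chrom,
                     pos = 1e5 * seq_len(m), minor = "G", major = "A",
                     stringsAsFactors = FALSE)
  sex <- ifelse(stats::runif(n) < spec$prop_male, "M", "F")
  subjects <- data.frame(subject_id = sprintf("S%04d", seq_len(n)), sex = sex,
                         stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, snps, subjects)
  attr(g, "maf_target") <- maf
  g
}

#' Generate clinical covariates
#'
#' Age uniform on 20-85 years; mean remifentanil infusion rate normal around
#' the 0.25 ug/kg/min protocol rate (SD 0.05, truncated positive);
#' end-of-surgery fentanyl 100 ug plus 50 ug increments (Poisson count,
#' mean 1); 2-h pain score an integer 0-10 centred near 3.
#'
#' @param spec A [cohort_spec()].
#' @param subject_ids Subject ids (defaults to the ids [gen_genotypes()]
#'   produces).
#' @return Data frame of class `covariate_table`: `subject_id`, `age_years`,
#'   `remi_rate_ug_kg_min`, `endsurg_fentanyl_ug`, `pain2h_score`.
#' @export
gen_covariates <- function(spec,
                           subject_ids = sprintf("S%04d", seq_len(spec$n_subjects))) {
  set.seed(.sub_seed(spec$seed, 2L))
  n <- length(subject_ids)
  age <- stats::runif(n, 20, 85)
  remi <- pmax(0.01, stats::rnorm(n, 0.25, 0.05))
  fent <- 100 + 50 * stats::rpois(n, 1)
  pain <- pmin(10L, pmax(0L, as.integer(round(stats::rnorm(n, 3, 2)))))
  out <- data.frame(subject_id = subject_ids, age_years = age,
                    remi_rate_ug_kg_min = remi, endsurg_fentanyl_ug = fent,
                    pain2h_score = pain, stringsAsFactors = FALSE)
  class(out) <- c("covariate_table", "data.frame")
  out
}

#' Covariate table as a numeric matrix keyed by subject id
#' @param covars A covariate table (data frame with `subject_id`).
#' @param vars Columns to keep (default all numeric columns).
#' @return Numeric matrix with subject ids as rownames.
#' @export
as_covariate_matrix <- function(covars, vars = NULL) {
  stopifnot("subject_id" %in% names(covars))
  num <- vapply(covars, is.numeric, logical(1))
  if (is.null(vars)) vars <- names(covars)[num & names(covars) != "subject_id"]
  X <- as.matrix(covars[, vars, drop = FALSE])
  rownames(X) <- covars$subject_id
  X
}

#' Generate latent per-subject MECs
#'
#' The latent log effect-site MEC is additive: intercept, per-copy genetic
#' effects of the configured causal SNPs, covariate effects, and a normal
#' residual; the latent MEC is its exponential (hence strictly positive).
#'
#' @param geno A [genotype_matrix()] from [gen_genotypes()].
#' @param covars A covariate table from [gen_covariates()].
#' @param spec The [cohort_spec()].
#' @return Data frame of class `latent_phenotype`: `subject_id`,
#'   `latent_mec` (ng/mL), and the log-scale components `lp_genetic`,
#'   `lp_covariate`, `lp_residual` (with `intercept` as an attribute;
#'   components plus intercept sum to `log(latent_mec)`).
#' @export
gen_latent_mec <- function(geno, covars, spec) {
  set.seed(.sub_seed(spec$seed, 3L))
  ids <- geno$subjects$subject_id
  n <- length(ids)
  lp_gen <- numeric(n)
  if (!is.null(spec$causal_snps)) {
    for (i in seq_len(nrow(spec$causal_snps))) {
      j <- spec$causal_snps$snp_index[i]
      lp_gen <- lp_gen + spec$causal_snps$beta[i] * geno$calls[, j]
    }
  }
  ce <- spec$covariate_effects
  cv <- covars[match(ids, covars$subject_id), ]
  lp_cov <- ce["age"] * cv$age_years +
    ce["remi_rate"] * cv$remi_rate_ug_kg_min +
    ce["endsurg_fentanyl"] * cv$endsurg_fentanyl_ug +
    ce["pain2h"] * cv$pain2h_score
  lp_res <- if (spec$noise_sd > 0) stats::rnorm(n, 0, spec$noise_sd) else numeric(n)
  lp <- spec$intercept + lp_gen + lp_cov + lp_res
  out <- data.frame(subject_id = ids, latent_mec = exp(lp),
                    lp_genetic = lp_gen, lp_covariate = unname(lp_cov),
                    lp_residual = lp_res, stringsAsFactors = FALSE)
  attr(out, "intercept") <- spec$intercept
  class(out) <- c("latent_phenotype", "data.frame")
  out
}

#' Closed-loop PCA dosing simulation for one subject
#'
#' Starting from the end-of-surgery bolus at t = 0, a demand is placed at
#' the first instant the effect-site concentration falls to the subject's
#' trigger threshold (latent MEC, optionally perturbed per demand by
#' multiplicative lognormal behavioural noise), subject to the pump rules:
#' at least `lockout_min` since the last delivered dose, at most
#' `max_per_hour` demands in any rolling 60 minutes, and a cumulative PCA
#' cap of `capacity_ug`. If the lockout or hourly cap delays a trigger the
#' demand fires at the earliest allowed instant. Trigger times are located
#' by bracketed root search on the analytic concentration curve (0.5-min
#' scan for the bracket). If even the initial bolus cannot raise the
#' effect-site concentration to the threshold, the history contains the
#' bolus only and is flagged.
#'
#' @param latent_mec Latent MEC (ng/mL), > 0.
#' @param params A [pk_params()] object.
#' @param spec The [cohort_spec()] (pump settings, bolus, horizon, noise).
#' @param subject_id Subject identifier for the returned history.
#' @return A [dosing_history()] with attributes `unconstrained` (logical per
#'   demand: trigger not delayed by pump rules), `exhausted` (reservoir
#'   emptied) and `unreachable` (threshold above achievable concentration).
#' @export
gen_dosing <- function(latent_mec, params, spec, subject_id = "S0001") {
  stopifnot(latent_mec > 0)
  h <- hybrid_constants(params)
  ps <- spec$pca_settings
  horizon <- spec$observation_end_min
  ev_t <- 0
  ev_d <- spec$initial_bolus_ug
  ev_k <- "initial_bolus"
  dem_t <- numeric()
  unconstrained <- logical()
  pca_total <- 0
  # Effect-site curve as four decaying exponential channels (three hybrid
  # exponents + ke0) with amplitudes folded forward at each dose, so one
  # evaluation costs O(1) in the number of past events. Equivalent to the
  # closed-form superposition of concentration_at() (property-tested).
  rates <- c(h$lambda, h$ke0)
  wts <- c(h$ce_coef, -sum(h$ce_coef))
  amp <- numeric(4)
  t_ref <- 0
  add_dose <- function(s, d) {
    amp <<- amp * exp(-rates * (s - t_ref)) + d * wts
    t_ref <<- s
  }
  ce_at <- function(t) {
    as.vector(exp(-outer(t - t_ref, rates)) %*% amp)
  }
  add_dose(0, spec$initial_bolus_ug)
  # can the initial bolus reach the (noise-free) threshold at all?
  t_probe <- seq(0, horizon, by = 0.5)
  ce0 <- spec$initial_bolus_ug * .unit_ce(h, t_probe)
  if (max(ce0) <= latent_mec) {
    hist <- dosing_history(subject_id, ev_t, ev_d, ev_k,
                           observation_end_min = horizon,
                           capacity_ug = ps$capacity_ug)
    attr(hist, "unconstrained") <- logical()
    attr(hist, "exhausted") <- FALSE
    attr(hist, "unreachable") <- TRUE
    return(hist)
  }
  repeat {
    if (pca_total + ps$demand_dose_ug > ps$capacity_ug + 1e-9) break
    thr <- latent_mec
    if (spec$behavior_noise_sd > 0)
      thr <- latent_mec * exp(stats::rnorm(1, 0, spec$behavior_noise_sd))
    last <- ev_t[length(ev_t)]
    # earliest time the pump will honour a press: lockout since the last
    # delivered dose (bolus included) plus the rolling-hour cap
    allowed <- last + ps$lockout_min
    k <- length(dem_t)
    if (k >= ps$max_per_hour)  # half-open rolling window; epsilon keeps the
      allowed <- max(allowed,  # boundary demand robustly outside it
                     dem_t[k - ps$max_per_hour + 1] + 60 + 1e-6)
    # trigger: first down-crossing of ce through thr after the last dose
    trig <- .first_downcross(ce_at, last, horizon, thr)
    if (is.na(trig)) {
      if (ce_at(max(last + 1e-9, allowed)) < thr && allowed < horizon) {
        # dose never restored the threshold: press at the earliest allowed time
        trig <- last
      } else break
    }
    t_dem <- max(trig, allowed)
    if (t_dem > horizon) break
    dem_t <- c(dem_t, t_dem)
    unconstrained <- c(unconstrained, trig >= allowed)
    ev_t <- c(ev_t, t_dem)
    ev_d <- c(ev_d, ps$demand_dose_ug)
    ev_k <- c(ev_k, "pca_demand")
    add_dose(t_dem, ps$demand_dose_ug)
    pca_total <- pca_total + ps$demand_dose_ug
  }
  hist <- dosing_history(subject_id, ev_t, ev_d, ev_k,
                         observation_end_min = horizon,
                         capacity_ug = ps$capacity_ug)
  attr(hist, "unconstrained") <- unconstrained
  attr(hist, "exhausted") <- pca_total + ps$demand_dose_ug > ps$capacity_ug
  attr(hist, "unreachable") <- FALSE
  hist
}

# first time in (t0, tmax] at which f crosses thr from above, located by a
# 0.5-min forward scan (chunked, so the curve is only evaluated up to the
# crossing) and uniroot refinement; NA if no such crossing
.first_downcross <- function(f, t0, tmax, thr, step = 0.5, chunk = 240L) {
  above <- f(t0 + 1e-9) > thr
  prev_t <- t0 + 1e-9
  start <- t0 + step
  while (start <= tmax) {
    grid <- seq(start, min(tmax, start + (chunk - 1) * step), by = step)
    vals <- f(grid)
    for (i in seq_along(grid)) {
      if (above && vals[i] <= thr) {
        return(stats::uniroot(function(t) f(t) - thr,
                              lower = prev_t, upper = grid[i],
                              tol = 1e-9)$root)
      }
      if (vals[i] > thr) above <- TRUE
      prev_t <- grid[i]
    }
    start <- grid[length(grid)] + step
  }
  NA_real_
}

#' Generate a complete synthetic cohort
#'
#' Composes [gen_genotypes()], [gen_covariates()], [gen_latent_mec()] and
#' (optionally) [gen_dosing()] for every subject, and returns a truth record
#' (causal SNPs and effects, per-subject latent MECs, per-subject dosing
#' flags) for recovery tests.
#'
#' @param spec A [cohort_spec()].
#' @param params A [pk_params()] object (default: the shipped
#'   `shafer_fentanyl` block).
#' @param dosing Simulate dosing histories (set `FALSE` to stop at latent
#'   phenotypes, e.g. for association-stage calibration runs).
#' @return A list of class `synthetic_cohort`: `geno`, `covars`, `latent`,
#'   `histories` (list of [dosing_history()] or `NULL`), `truth`, `spec`.
#' @export
gen_cohort <- function(spec, params = pk_params_from_config(), dosing = TRUE) {
  geno <- gen_genotypes(spec)
  covars <- gen_covariates(spec, geno$subjects$subject_id)
  latent <- gen_latent_mec(geno, covars, spec)
  histories <- NULL
  flags <- NULL
  if (dosing) {
    set.seed(.sub_seed(spec$seed, 4L))
    histories <- lapply(seq_len(spec$n_subjects), function(i) {
      gen_dosing(latent$latent_mec[i], params, spec,
                 subject_id = latent$subject_id[i])
    })
    names(histories) <- latent$subject_id
    flags <- data.frame(
      subject_id = latent$subject_id,
      n_demands = vapply(histories, function(x) sum(x$events$kind == "pca_demand"), integer(1)),
      n_unconstrained = vapply(histories, function(x) sum(attr(x, "unconstrained")), integer(1)),
      exhausted = vapply(histories, function(x) attr(x, "exhausted"), logical(1)),
      unreachable = vapply(histories, function(x) attr(x, "unreachable"), logical(1)),
      stringsAsFactors = FALSE)
  }
  truth <- list(causal_snps = spec$causal_snps,
                causal_ids = if (is.null(spec$causal_snps)) character() else
                  geno$snps$id[spec$causal_snps$snp_index],
                latent = latent, dosing_flags = flags, seed = spec$seed)
  structure(list(geno = geno, covars = covars, latent = latent,
                 histories = histories, truth = truth, spec = spec),
            class = "synthetic_cohort")
}
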