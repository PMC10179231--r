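#' Three-compartment pharmacokinetic parameters with an effect site
#'
#' Constructs and validates the parameter set of a linear mammillary
#' three-compartment disposition model (central volume `v1`, micro rate
#' constants `k10`, `k12`, `k21`, `k13`, `k31`) augmented with a first-order
#' effect compartment (`ke0`). Units are minutes, litres and micrograms
#' throughout; 1 ug/L is reported as 1 ng/mL.
#'
#' A degenerate configuration with `k12 = k13 = 0` is allowed and reduces to
#' one-compartment kinetics. Because transfer constants must stay strictly
#' positive, "zero" is represented internally by a negligible positive value.
#'
#' @param v1 Central volume of distribution (L).
#' @param k10,k12,k21,k13,k31 Micro rate constants (1/min); `k12`/`k13` may be
#'   0 to drop a peripheral compartment.
#' @param ke0 Effect-site equilibration constant (1/min).
#' @return An object of class `pk_params`.
#' @examples
#' pk_params(v1 = 10, k10 = 0.1, k12 = 0, k21 = 0.05, k13 = 0, k31 = 0.02,
#'           ke0 = 0.5)
#' @export
pk_params <- function(v1, k10, k12, k21, k13, k31, ke0) {
  vals <- c(v1 = v1, k10 = k10, k12 = k12, k21 = k21, k13 = k13, k31 = k31,
            ke0 = ke0)
  if (any(!is.finite(vals))) stop("pk_params: all parameters must be finite")
  if (any(vals[c("v1", "k10", "k21", "k31", "ke0")] <= 0))
    stop("pk_params: v1, k10, k21, k31 and ke0 must be strictly positive")
  if (k12 < 0 || k13 < 0) stop("pk_params: k12 and k13 must be >= 0")
  structure(as.list(vals), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Three-compartment PK parameters (+ effect site)\n")
  cat(sprintf("  v1 = %g L; k10 = %g, k12 = %g, k21 = %g, k13 = %g, k31 = %g, ke0 = %g (1/min)\n",
              x$v1, x$k10, x$k12, x$k21, x$k13, x$k31, x$ke0))
  invisible(x)
}

#' Load a named PK parameter set from a YAML configuration file
#'
#' Parameter sets are stored as named blocks in a YAML file; the package ships
#' a default file with a representative fentanyl parameterization
#' (`"shafer_fentanyl"`). The engine itself never hard-codes drug constants.
#'
#' @param name Block name in the file.
#' @param file YAML file path; defaults to the file shipped with the package.
#' @param weight Optional body weight (kg). When given, `v1` is scaled
#'   linearly by `weight / ref_weight_kg` (a simple allometric hook, off when
#'   `weight` is `NULL`).
#' @return A `pk_params` object.
#' @export
pk_params_from_config <- function(name = "shafer_fentanyl",
                                  file = system.file("extdata", "pk_params.yaml",
                                                     package = "mecgwas"),
                                  weight = NULL) {
  cfg <- yaml::read_yaml(file)
  if (is.null(cfg[[name]]))
    stop(sprintf("no PK parameter block named '%s' in %s", name, file))
  b <- cfg[[name]]
  v1 <- b$v1
  if (!is.null(weight)) {
    ref <- if (is.null(b$ref_weight_kg)) 70 else b$ref_weight_kg
    v1 <- v1 * weight / ref
  }
  pk_params(v1 = v1, k10 = b$k10, k12 = b$k12, k21 = b$k21,
            k13 = b$k13, k31 = b$k31, ke0 = b$ke0)
}

# Smallest positive stand-in for a structurally absent transfer constant.
.pk_eps <- 1e-12

# Relative spacing below which exponents are treated as coincident.
.pk_degenerate_tol <- 1e-9

#' Closed-form hybrid disposition constants
#'
#' Diagonalizes the 3x3 disposition rate matrix of the mammillary model and
#' returns the hybrid exponents (negated eigenvalues) together with the plasma
#' unit-impulse coefficients, so that a unit (1 ug) bolus gives
#' `Cp(t) = A exp(-l1 t) + B exp(-l2 t) + C exp(-l3 t)` with
#' `A + B + C = 1/v1`. Effect-site convolution coefficients for the same unit
#' bolus are also returned: `Ce(t) = sum_i ce_coef_i (exp(-l_i t) - exp(-ke0 t))`
#' with `ce_coef_i = coef_i * ke0 / (ke0 - l_i)`.
#'
#' Exactly coincident exponents (relative spacing below 1e-9, a measure-zero
#' configuration) are resolved by a tiny relative perturbation of the rate
#' constants, with a warning.
#'
#' @param params A [pk_params()] object.
#' @return A list of class `hybrid_disposition` with elements `lambda` (three
#'   positive exponents, decreasing), `coef` (plasma coefficients, 1/L),
#'   `ke0` and `ce_coef`.
#' @export
hybrid_constants <- function(params) {
  stopifnot(inherits(params, "pk_params"))
  k12 <- max(params$k12, .pk_eps)
  k13 <- max(params$k13, .pk_eps)
  h <- .hybrid_raw(params$v1, params$k10, k12, params$k21, k13, params$k31)
  rel <- function(a, b) abs(a - b) / max(abs(a), abs(b))
  lam <- h$lambda
  if (rel(lam[1], lam[2]) < .pk_degenerate_tol ||
      rel(lam[2], lam[3]) < .pk_degenerate_tol) {
    warning("coincident disposition exponents; perturbing rate constants by 1e-9 (relative)")
    h <- .hybrid_raw(params$v1, params$k10 * (1 + 1e-9), k12,
                     params$k21 * (1 - 1e-9), k13, params$k31 * (1 + 2e-9))
    lam <- h$lambda
  }
  ke0 <- params$ke0
  if (min(abs(ke0 - lam) / pmax(ke0, lam)) < .pk_degenerate_tol) {
    warning("ke0 coincides with a disposition exponent; perturbing ke0 by 1e-9 (relative)")
    ke0 <- ke0 * (1 + 1e-9)
  }
  structure(list(lambda = lam, coef = h$coef, ke0 = ke0,
                 ce_coef = h$coef * ke0 / (ke0 - lam)),
            class = "hybrid_disposition")
}

.hybrid_raw <- function(v1, k10, k12, k21, k13, k31) {
  K <- matrix(c(-(k10 + k12 + k13), k21, k31,
                k12, -k21, 0,
                k13, 0, -k31), nrow = 3, byrow = TRUE)
  eg <- eigen(K)
  lam <- -Re(eg$values)
  V <- Re(eg$vectors)
  # unit amount in the central compartment at t = 0+
  w <- solve(V, c(1, 0, 0))
  coef <- V[1, ] * w / v1
  ord <- order(lam, decreasing = TRUE)
  list(lambda = lam[ord], coef = coef[ord])
}

# Unit-bolus (1 ug) plasma and effect-site responses at elapsed times tau >= 0.
.unit_cp <- function(h, tau) {
  out <- numeric(length(tau))
  pos <- tau >= 0
  if (any(pos)) {
    tt <- tau[pos]
    out[pos] <- exp(-outer(tt, h$lambda)) %*% h$coef
  }
  out
}

.unit_ce <- function(h, tau) {
  out <- numeric(length(tau))
  pos <- tau >= 0
  if (any(pos)) {
    tt <- tau[pos]
    out[pos] <- (exp(-outer(tt, h$lambda)) - exp(-tt * h$ke0)) %*% h$ce_coef
  }
  # clamp tiny negative round-off
  out[out < 0 & out > -1e-12] <- 0
  out
}

#' A timed fentanyl dosing history for one subject
#'
#' @param subject_id Subject identifier (scalar).
#' @param time_min Numeric vector of dose times, minutes since end of surgery.
#' @param dose_ug Dose sizes (ug), same length as `time_min`.
#' @param kind Character vector, each `"initial_bolus"` or `"pca_demand"`.
#' @param observation_end_min Observation horizon (min), default 1440.
#' @param capacity_ug PCA reservoir capacity used for validation (ug).
#' @return An object of class `dosing_history` with an `events` data frame
#'   sorted by time.
#' @export
dosing_history <- function(subject_id, time_min = numeric(), dose_ug = numeric(),
                           kind = character(), observation_end_min = 1440,
                           capacity_ug = 1000) {
  stopifnot(length(time_min) == length(dose_ug),
            length(time_min) == length(kind))
  if (length(time_min)) {
    if (any(!is.finite(time_min)) || any(time_min < 0))
      stop("dosing_history: event times must be finite and >= 0")
    if (any(dose_ug <= 0)) stop("dosing_history: doses must be > 0")
    if (!all(kind %in% c("initial_bolus", "pca_demand")))
      stop("dosing_history: kind must be 'initial_bolus' or 'pca_demand'")
  }
  ord <- order(time_min)
  ev <- data.frame(time_min = time_min[ord], dose_ug = dose_ug[ord],
                   kind = kind[ord], stringsAsFactors = FALSE)
  pca_total <- sum(ev$dose_ug[ev$kind == "pca_demand"])
  if (pca_total > capacity_ug + 1e-9)
    stop(sprintf("dosing_history: cumulative PCA dose %.1f ug exceeds capacity %.1f ug",
                 pca_total, capacity_ug))
  structure(list(subject_id = subject_id, events = ev,
                 observation_end_min = observation_end_min),
            class = "dosing_history")
}

#' @export
print.dosing_history <- function(x, ...) {
  cat(sprintf("Dosing history for subject %s: %d events over %g min (%g ug total)\n",
              x$subject_id, nrow(x$events), x$observation_end_min,
              sum(x$events$dose_ug)))
  invisible(x)
}

#' Concentration at a time point by bolus superposition
#'
#' Evaluates the closed-form plasma or effect-site concentration at time `t`
#' as the superposition of all bolus responses. `side = "pre"` returns the
#' left limit (a bolus given at exactly `t` is excluded — the convention used
#' to read the concentration "immediately before" a demand); `side = "post"`
#' includes it. A bolus is an instantaneous jump of `dose/v1` in central
#' concentration, so plasma differs between the two sides at an event instant
#' while the effect site, which is continuous, does not.
#'
#' @param history A [dosing_history()].
#' @param params A [pk_params()] object (or a precomputed
#'   [hybrid_constants()] result).
#' @param t Time(s) in minutes, >= 0; vectorized.
#' @param site `"plasma"` or `"effect"`.
#' @param side `"pre"` (left limit) or `"post"`.
#' @return Concentration(s) in ng/mL.
#' @export
concentration_at <- function(history, params, t, site = c("plasma", "effect"),
                             side = c("post", "pre")) {
  site <- match.arg(site)
  side <- match.arg(side)
  if (any(t < 0)) stop("concentration_at: t must be >= 0")
  h <- if (inherits(params, "hybrid_disposition")) params else hybrid_constants(params)
  ev <- history$events
  if (!nrow(ev)) return(numeric(length(t)) + 0)
  unit <- if (site == "plasma") .unit_cp else .unit_ce
  vapply(t, function(ti) {
    keep <- if (side == "pre") ev$time_min < ti else ev$time_min <= ti
    if (!any(keep)) return(0)
    sum(ev$dose_ug[keep] * unit(h, ti - ev$time_min[keep]))
  }, numeric(1))
}

#' Simulate dense plasma and effect-site concentration profiles
#'
#' Evaluates the closed-form solution on a regular grid over the observation
#' window, plus the exact pre- and post-dose values at every event time.
#'
#' @param history A [dosing_history()].
#' @param params A [pk_params()] object.
#' @param grid Time step (min), > 0.
#' @return A data frame of class `conc_profile` with columns `subject_id`,
#'   `time_min`, `side` (`"pre"` only duplicated at event instants),
#'   `cp_ng_ml`, `ce_ng_ml`.
#' @export
simulate_profile <- function(history, params, grid = 1) {
  if (grid <= 0) stop("simulate_profile: grid must be > 0")
  h <- hybrid_constants(params)
  tg <- seq(0, history$observation_end_min, by = grid)
  tev <- unique(history$events$time_min)
  times <- c(tg, tev)
  side <- c(rep("post", length(tg)), rep("pre", length(tev)))
  ord <- order(times, side == "post")  # pre before post at equal times
  times <- times[ord]; side <- side[ord]
  cp <- numeric(length(times)); ce <- numeric(length(times))
  for (s in c("pre", "post")) {
    i <- side == s
    if (any(i)) {
      cp[i] <- concentration_at(history, h, times[i], "plasma", s)
      ce[i] <- concentration_at(history, h, times[i], "effect", s)
    }
  }
  out <- data.frame(subject_id = history$subject_id, time_min = times,
                    side = side, cp_ng_ml = cp, ce_ng_ml = ce,
                    stringsAsFactors = FALSE)
  class(out) <- c("conc_profile", "data.frame")
  out
}
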