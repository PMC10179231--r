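test_that("hybrid constants satisfy the spectral identities of the rate matrix", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_pk()
    h <- hybrid_constants(p)
    expect_equal(sum(h$lambda), p$k10 + p$k12 + p$k21 + p$k13 + p$k31,
                 tolerance = 1e-10)
    # determinant identity, checked against a numeric determinant oracle
    K <- matrix(c(-(p$k10 + p$k12 + p$k13), p$k21, p$k31,
                  p$k12, -p$k21, 0,
                  p$k13, 0, -p$k31), 3, 3, byrow = TRUE)
    expect_equal(prod(h$lambda), -det(K), tolerance = 1e-10)
    expect_equal(prod(h$lambda), p$k10 * p$k21 * p$k31, tolerance = 1e-10)
    expect_equal(sum(h$coef), 1 / p$v1, tolerance = 1e-10)
    expect_true(all(h$lambda > 0))
  }
})

test_that("k12 = k13 = 0 collapses to one-compartment kinetics", {
  h <- hybrid_constants(pk_1cpt())
  # one exponent carries all the weight, at k10, with coefficient 1/v1
  main <- which.max(abs(h$coef))
  expect_equal(h$lambda[main], 0.1, tolerance = 1e-9)
  expect_equal(h$coef[main], 0.1, tolerance = 1e-9)
  expect_lt(max(abs(h$coef[-main])), 1e-9)
})

test_that("parameter validation rejects non-positive values", {
  expect_error(pk_params(0, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1), "positive")
  expect_error(pk_params(10, -0.1, 0.1, 0.1, 0.1, 0.1, 0.1), "positive")
  expect_error(pk_params(10, 0.1, -0.1, 0.1, 0.1, 0.1, 0.1), ">= 0")
})

test_that("a ke0 coinciding with a disposition exponent is perturbed with a warning", {
  p <- pk_params(10, 0.1, 0, 0.05, 0, 0.02, ke0 = 0.1)
  expect_warning(h <- hybrid_constants(p), "perturb")
  expect_true(all(is.finite(h$ce_coef)))
  # near-coincident disposition exponents (k21 = k10 in the one-compartment
  # limit) still yield finite, consistent constants
  p2 <- pk_params(10, 0.1, 0, 0.1, 0, 0.02, 0.5)
  h2 <- hybrid_constants(p2)
  expect_equal(sum(h2$coef), 1 / 10, tolerance = 1e-9)
})

test_that("single-bolus concentrations match the mono-exponential closed form", {
  p <- pk_1cpt(ke0 = 0.5)
  hist <- dosing_history("s", 0, 100, "initial_bolus")
  expect_equal(concentration_at(hist, p, 10, "plasma", "pre"),
               10 * exp(-1), tolerance = 1e-9)
  # effect site: two-exponential convolution response
  expect_equal(concentration_at(hist, p, 10, "effect", "pre"),
               10 * (0.5 / 0.4) * (exp(-1) - exp(-5)), tolerance = 1e-9)
})

test_that("pre excludes and post includes a bolus at exactly t", {
  p <- pk_1cpt()
  hist <- dosing_history("s", c(0, 10), c(100, 20),
                         c("initial_bolus", "pca_demand"))
  pre <- concentration_at(hist, p, 10, "plasma", "pre")
  post <- concentration_at(hist, p, 10, "plasma", "post")
  expect_equal(pre, 10 * exp(-1), tolerance = 1e-9)
  expect_equal(post - pre, 20 / 10, tolerance = 1e-9)
  # effect site is continuous across a dose instant
  expect_equal(concentration_at(hist, p, 10, "effect", "pre"),
               concentration_at(hist, p, 10, "effect", "post"),
               tolerance = 1e-12)
})

test_that("superposition and dose proportionality hold", {
  set.seed(21)
  p <- random_pk()
  h1 <- dosing_history("a", c(0, 30), c(100, 20),
                       c("initial_bolus", "pca_demand"))
  h2 <- dosing_history("b", c(10, 45), c(20, 20),
                       c("pca_demand", "pca_demand"))
  both <- dosing_history("ab", c(0, 10, 30, 45), c(100, 20, 20, 20),
                         c("initial_bolus", rep("pca_demand", 3)))
  ts <- seq(0, 120, by = 7)
  for (site in c("plasma", "effect")) {
    expect_equal(concentration_at(both, p, ts, site),
                 concentration_at(h1, p, ts, site) +
                   concentration_at(h2, p, ts, site), tolerance = 1e-10)
  }
  scaled <- dosing_history("a2", c(0, 30), 3 * c(100, 20),
                           c("initial_bolus", "pca_demand"))
  expect_equal(concentration_at(scaled, p, ts, "effect"),
               3 * concentration_at(h1, p, ts, "effect"), tolerance = 1e-10)
})

test_that("profiles are nonnegative, start at zero effect, and lag plasma", {
  set.seed(31)
  p <- random_pk()
  hist <- dosing_history("s", 0, 100, "initial_bolus")
  prof <- simulate_profile(hist, p, grid = 0.5)
  expect_true(all(prof$cp_ng_ml >= 0))
  expect_true(all(prof$ce_ng_ml >= 0))
  expect_equal(prof$ce_ng_ml[prof$time_min == 0 & prof$side == "post"], 0)
  # effect-site peak strictly after t=0 and below the plasma peak
  ipk <- which.max(prof$ce_ng_ml)
  expect_gt(prof$time_min[ipk], 0)
  expect_lt(max(prof$ce_ng_ml), max(prof$cp_ng_ml))
})

test_that("empty history gives an all-zero profile", {
  p <- pk_1cpt()
  hist <- dosing_history("s")
  prof <- simulate_profile(hist, p, grid = 60)
  expect_true(all(prof$cp_ng_ml == 0) && all(prof$ce_ng_ml == 0))
})

test_that("analytic solution matches a stiff ODE integration of the 4-state system", {
  skip_if_not_installed("deSolve")
  set.seed(41)
  ode_profile <- function(hist, p, times) {
    deriv <- function(t, y, parms) {
      with(as.list(parms), {
        da1 <- -(k10 + k12 + k13) * y[1] + k21 * y[2] + k31 * y[3]
        da2 <- k12 * y[1] - k21 * y[2]
        da3 <- k13 * y[1] - k31 * y[3]
        dce <- ke0 * (y[1] / v1 - y[4])
        list(c(da1, da2, da3, dce))
      })
    }
    ev <- data.frame(var = "a1", time = hist$events$time_min,
                     value = hist$events$dose_ug, method = "add")
    tt <- sort(unique(c(times, ev$time)))
    out <- deSolve::lsoda(c(a1 = 0, a2 = 0, a3 = 0, ce = 0), tt, deriv,
                          unlist(p[1:7]),
                          events = list(data = ev),
                          rtol = 1e-11, atol = 1e-12)
    list(t = out[, 1], cp = out[, 2] / p$v1, ce = out[, 5])
  }
  for (i in 1:8) {
    p <- random_pk()
    hist <- random_history(n_events = sample(2:10, 1))
    times <- sort(c(runif(15, 1, 700), hist$events$time_min + 0.25))
    ode <- ode_profile(hist, p, times)
    keep <- ode$t %in% times
    cp <- concentration_at(hist, p, ode$t[keep], "plasma", "post")
    ce <- concentration_at(hist, p, ode$t[keep], "effect", "post")
    scale <- max(cp)
    expect_lt(max(abs(cp - ode$cp[keep])) / scale, 1e-6)
    expect_lt(max(abs(ce - ode$ce[keep])) / scale, 1e-6)
  }
})

test_that("large ke0 makes the effect site track plasma", {
  p_base <- pk_params(10, 0.1, 0.3, 0.1, 0.2, 0.03, ke0 = 50)
  hist <- dosing_history("s", 0, 100, "initial_bolus")
  ts <- seq(5, 300, by = 10)
  cp <- concentration_at(hist, p_base, ts, "plasma")
  ce <- concentration_at(hist, p_base, ts, "effect")
  expect_lt(max(abs(ce - cp) / cp), 0.05)
})
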