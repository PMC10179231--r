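# shared fixtures built in code

# one-compartment configuration (k12 = k13 = 0) used in closed-form checks
pk_1cpt <- function(ke0 = 0.5) {
  pk_params(v1 = 10, k10 = 0.1, k12 = 0, k21 = 0.05, k13 = 0, k31 = 0.02,
            ke0 = ke0)
}

# representative three-compartment fentanyl parameter set shipped as config
pk_fent <- function() pk_params_from_config("shafer_fentanyl")

random_pk <- function() {
  pk_params(v1 = runif(1, 3, 30),
            k10 = runif(1, 0.02, 0.3),
            k12 = runif(1, 0.05, 0.6),
            k21 = runif(1, 0.02, 0.4),
            k13 = runif(1, 0.02, 0.4),
            k31 = runif(1, 0.005, 0.1),
            ke0 = runif(1, 0.05, 0.6))
}

random_history <- function(n_events = sample(1:20, 1), horizon = 720) {
  times <- sort(runif(n_events, 0, horizon * 0.8))
  times[1] <- 0
  kinds <- c("initial_bolus", rep("pca_demand", n_events - 1))
  doses <- c(runif(1, 50, 150), rep(20, n_events - 1))
  dosing_history("r1", times, doses, kinds, observation_end_min = horizon)
}

# small deterministic genotype fixture: 3 SNPs x 8 subjects
toy_geno <- function() {
  calls <- rbind(c(0, 1, 2), c(1, 1, 0), c(2, 0, 1), c(0, 0, 0),
                 c(1, 2, 1), c(0, 1, 2), c(2, 2, 0), c(1, 0, 1))
  snps <- data.frame(id = c("rsA", "rsB", "rsC"),
                     chrom = c("1", "2", "X"), pos = c(100, 200, 300),
                     minor = "G", major = "A", stringsAsFactors = FALSE)
  subjects <- data.frame(subject_id = paste0("P", 1:8),
                         sex = c("F", "M", "F", "F", "M", "F", "F", "M"),
                         stringsAsFactors = FALSE)
  genotype_matrix(calls, snps, subjects)
}

# brute-force OLS via normal equations, independent of lm.fit/QR
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  tv <- b / se
  list(beta = as.vector(b), se = se, t = as.vector(tv),
       p = 2 * pt(abs(tv), df, lower.tail = FALSE), df = df)
}
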