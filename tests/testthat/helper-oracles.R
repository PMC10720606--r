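# Independent oracles and shared simulation machinery for the test suite.

library(glmnet)

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# overflow-safe logistic surrogate, written out independently of the package
phi_ref <- function(t) ifelse(t > 0, log1p(exp(-t)), -t + log1p(exp(t)))

surr_obj_ref <- function(x, op, om, beta, lambda) {
  t <- drop(x %*% beta)
  mean(op * phi_ref(t) + om * phi_ref(-t)) + lambda * sum(abs(beta))
}

wls_obj_ref <- function(xm, xj, h, w, lambda) {
  mean(h * (xj - drop(xm %*% w))^2) + lambda * sum(abs(w))
}

# General-purpose convex-solver oracle for the penalized surrogate problem:
# the objective is a case-weighted binomial lasso on stacked pseudo-rows
# (+1 with weight omega_plus, -1 with weight omega_minus), which glmnet
# solves at penalty lambda * n / sum(weights).
oracle_surrogate <- function(x, op, om, lambda) {
  n <- nrow(x)
  xx <- rbind(x, x)
  yy <- c(rep(1, n), rep(0, n))
  w <- c(op, om)
  lg <- lambda * n / sum(w)
  fit <- glmnet(xx, yy, family = "binomial", weights = w, intercept = FALSE,
                standardize = FALSE, lambda = lg * c(8, 4, 2, 1),
                thresh = 1e-14, maxit = 1e6)
  as.numeric(coef(fit, s = lg, exact = TRUE, x = xx, y = yy, weights = w))[-1]
}

# Oracle for the weighted least-squares lasso (observation-weighted gaussian
# lasso; glmnet's objective carries a 1/2, hence lambda * n / (2 sum(h))).
oracle_wls <- function(xm, xj, h, lambda) {
  lg <- lambda * nrow(xm) / (2 * sum(h))
  fit <- glmnet(xm, xj, weights = h, intercept = FALSE, standardize = FALSE,
                lambda = lg * c(8, 4, 2, 1), thresh = 1e-14, maxit = 1e6)
  as.numeric(coef(fit, s = lg, exact = TRUE, x = xm, y = xj, weights = h))[-1]
}

# Brute-force sample distance correlation via explicit double centering.
dcor_ref <- function(x, y) {
  A <- as.matrix(dist(x))
  B <- as.matrix(dist(y))
  Ac <- sweep(sweep(A, 1, rowMeans(A)), 2, colMeans(A)) + mean(A)
  Bc <- sweep(sweep(B, 1, rowMeans(B)), 2, colMeans(B)) + mean(B)
  den <- sqrt(mean(Ac^2) * mean(Bc^2))
  if (den <= 0) return(0)
  v <- mean(Ac * Bc) / den
  if (v <= 0) 0 else sqrt(v)
}

# oracle nuisance functions for a benchmark scenario
oracle_nuisances <- function(spec) {
  fns <- pearlitr:::scenario_fns(spec)
  list(pi = function(newx) fns$pi1(newx),
       q = function(newx, arm) arm * fns$delta(newx) + fns$smean(newx),
       delta = fns$delta, smean = fns$smean)
}

# Shared Monte-Carlo runs for the null-coordinate calibration study
# (Scenario I, xi = 0.7, n = 800, p = 100, K = 2, penalized-parametric
# nuisances, trimming [0.1, 0.9]); the coverage check reuses the same runs.
.calib_cache <- new.env(parent = emptyenv())

null_calibration_runs <- function(n_reps = 200, seed = 20240801) {
  key <- sprintf("calib_%d_%d", n_reps, seed)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_reps)
  rej <- matrix(NA, n_reps, 4)
  cov0 <- matrix(NA, n_reps, 4)
  for (r in seq_len(n_reps)) {
    sc <- itr_scenario("I", n = 800, p = 100, xi = 0.7, seed = seeds[r])
    dat <- sim_itr(sc)
    fit <- pearl(dat$x, dat$a, dat$y, K = 2,
                 propensity = "penalized_logistic", outcome = "penalized_linear",
                 trim = c(0.1, 0.9), seed = seeds[r])
    inf <- pearl_infer(fit, coords = 5:8, level = 0.95, fdr = FALSE,
                       seed = seeds[r])
    rej[r, ] <- inf$p_value < 0.05
    cov0[r, ] <- inf$conf_lo <= 0 & inf$conf_hi >= 0
  }
  .calib_cache[[key]] <- list(reject = rej, cover0 = cov0)
  .calib_cache[[key]]
}
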