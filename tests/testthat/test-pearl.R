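test_that("pooled coefficients are the exact fold average and folds partition rows", {
  sc <- itr_scenario("I", n = 300, p = 8, xi = 0.7, seed = 41)
  dat <- sim_itr(sc)
  orc <- oracle_nuisances(sc)
  fit <- pearl(dat$x, dat$a, dat$y, K = 3, propensity = orc$pi, outcome = orc$q,
               trim = NULL, lambda = 0.05, seed = 41)
  bmat <- vapply(fit$fold, `[[`, numeric(8), "beta")
  expect_equal(unname(coef(fit)), unname(rowMeans(bmat)))
  idx <- unlist(lapply(fit$fold, `[[`, "index"))
  expect_identical(sort(idx), 1:300)
  expect_equal(length(unique(idx)), 300)
  # reproducibility
  fit2 <- pearl(dat$x, dat$a, dat$y, K = 3, propensity = orc$pi, outcome = orc$q,
                trim = NULL, lambda = 0.05, seed = 41)
  expect_identical(coef(fit), coef(fit2))
})

test_that("permuting rows within folds leaves the pooled estimate unchanged", {
  sc <- itr_scenario("I", n = 240, p = 6, xi = 0.7, seed = 42)
  dat <- sim_itr(sc)
  orc <- oracle_nuisances(sc)
  fit <- pearl(dat$x, dat$a, dat$y, K = 2, propensity = orc$pi, outcome = orc$q,
               trim = NULL, lambda = 0.04, seed = 42)
  # permutation that maps every fold onto itself
  perm <- seq_len(240)
  for (f in fit$plan$folds) perm[f] <- f[c(length(f), seq_len(length(f) - 1))]
  fitp <- pearl(dat$x[perm, ], dat$a[perm], dat$y[perm], K = 2,
                propensity = orc$pi, outcome = orc$q, trim = NULL,
                lambda = 0.04, seed = 42)
  expect_equal(unname(coef(fit)), unname(coef(fitp)), tolerance = 1e-6)
})

test_that("the fitted rule recovers the optimal direction with data-driven nuisances", {
  sc <- itr_scenario("I", n = 2000, p = 50, xi = 0.7, seed = 43)
  dat <- sim_itr(sc)
  fit <- pearl(dat$x, dat$a, dat$y, K = 2, propensity = "penalized_logistic",
               outcome = "penalized_linear", seed = 43)
  expect_gte(cosine(coef(fit), sc$beta_opt), 0.9)
  test <- sim_itr(sc, seed = 44)
  agree <- mean(predict(fit, test$x) == oracle_rule(sc, test$x))
  expect_gte(agree, 0.92)
})

test_that("rule predictions follow the sign convention and are scale-free", {
  sc <- itr_scenario("I", n = 200, p = 6, xi = 0.7, seed = 45)
  dat <- sim_itr(sc)
  orc <- oracle_nuisances(sc)
  # an overwhelming penalty gives beta = 0, hence all decisions +1
  fit0 <- pearl(dat$x, dat$a, dat$y, propensity = orc$pi, outcome = orc$q,
                trim = NULL, lambda = 50, seed = 45)
  expect_identical(unname(coef(fit0)), rep(0, 6))
  expect_identical(predict(fit0, dat$x), rep(1, 200))
  fit <- pearl(dat$x, dat$a, dat$y, propensity = orc$pi, outcome = orc$q,
               trim = NULL, lambda = 0.05, seed = 45)
  d1 <- predict(fit, dat$x)
  fit_scaled <- fit
  fit_scaled$coefficients <- 3.7 * fit$coefficients
  expect_identical(predict(fit_scaled, dat$x), d1)
  expect_error(predict(fit, dat$x[, 1:5]), "covariates")
})

test_that("degenerate and invalid inputs are rejected with context", {
  x <- matrix(rnorm(200), 50, 4)
  expect_error(pearl(x, rep(1, 50), rnorm(50), seed = 1), "single treatment arm|both")
  expect_error(pearl(x, rep(c(1, -1), 25), c(rnorm(49), NA), seed = 1), "missing")
  expect_error(pearl(x, rep(c(1, -1), 25), rnorm(50), trim = c(0.9, 0.1)), "trim")
})
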