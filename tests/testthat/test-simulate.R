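test_that("scenario specification enforces the fixed design", {
  sc <- itr_scenario("I", n = 100, p = 10, xi = 0.7, seed = 1)
  expect_equal(sc$beta_opt, c(1, 1, -1, -1, rep(0, 6)))
  expect_equal(sc$beta_s, c(-1, -1, 1, -1, rep(0, 6)))
  expect_equal(sc$beta_pi, c(1, -1, rep(0, 8)))
  expect_error(itr_scenario("I", n = 100, p = 3), "p")
  expect_error(itr_scenario("II", n = 100, p = 3), "p")
  expect_error(itr_scenario("I", n = 100, p = 10, xi = 0.05), "xi")
  expect_error(itr_scenario("I", n = 100, p = 10, xi = 1.5), "xi")
})

test_that("simulation is deterministic given a seed and well formed", {
  sc <- itr_scenario("II", n = 300, p = 8, xi = 0.5, seed = 42)
  d1 <- sim_itr(sc)
  d2 <- sim_itr(sc)
  expect_identical(d1, d2)
  expect_true(all(d1$a %in% c(-1, 1)))
  expect_true(all(table(d1$a) > 0))
  expect_false(anyNA(d1$y))
  expect_identical(d1$column_names, paste0("x", 1:8))
  # a supplied seed must not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(sim_itr(sc)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("the optimal rule is sgn(x'beta_opt) with sgn(0) = +1", {
  sc <- itr_scenario("I", n = 10, p = 6, xi = 0.7)
  e <- function(j) replace(rep(0, 6), j, 1)
  expect_equal(oracle_rule(sc, e(1)), 1)
  expect_equal(oracle_rule(sc, e(3)), -1)
  expect_equal(oracle_rule(sc, rep(0, 6)), 1)
  expect_error(oracle_rule(sc, rep(0, 5)), "covariates")
})

test_that("scenario II treatment effect vanishes exactly on the boundary", {
  sc <- itr_scenario("II", n = 10, p = 6, xi = 0.6)
  fns <- pearlitr:::scenario_fns(sc)
  # rows with x1 + x2 - x3 - x4 = 0
  x <- rbind(c(1, 1, 1, 1, 0, 0), c(2, -1, 3, -2, 5, -5), c(0, 0, 0, 0, 1, 1))
  expect_equal(fns$delta(x), rep(0, 3))
  # and the modulating factor keeps Delta increasing in x'beta_opt elsewhere
  xx <- matrix(rnorm(600), 100, 6)
  u <- xx[, 1] + xx[, 2] - xx[, 3] - xx[, 4]
  expect_true(all(sign(fns$delta(xx)) == sign(pnorm(0.6 * u) - 0.5)))
})

test_that("generated treatment frequency matches the design propensity", {
  sc <- itr_scenario("I", n = 2e5, p = 5, xi = 0.7, seed = 314)
  dat <- sim_itr(sc)
  # E[A] = 2 E[expit(0.4 Z)] - 1 with Z = X1 - X2 ~ N(0, 2), by numerical
  # integration (the integral is 1/2 by symmetry, so the target is 0)
  ea <- 2 * integrate(function(z) plogis(0.4 * z) * dnorm(z, sd = sqrt(2)),
                      -Inf, Inf)$value - 1
  expect_equal(ea, 0, tolerance = 1e-8)
  expect_lt(abs(mean(dat$a) - ea), 3 / sqrt(2e5))
})

test_that("generator is self-consistent: Y - S(X) regresses on A*Delta(X) with slope 1", {
  sc <- itr_scenario("II", n = 2e4, p = 6, xi = 0.8, seed = 99)
  dat <- sim_itr(sc)
  fns <- pearlitr:::scenario_fns(sc)
  z <- dat$y - fns$smean(dat$x)
  w <- dat$a * fns$delta(dat$x)
  slope <- sum(w * z) / sum(w^2)
  expect_equal(slope, 1, tolerance = 0.02)
})

test_that("Monte-Carlo values match closed forms for simple rules", {
  sc <- itr_scenario("I", n = 100, p = 20, xi = 0.7)
  # constant rule +1: value = E[Delta + S] = 0 (centered covariates)
  v_const <- oracle_value(sc, function(x) rep(1, nrow(x)), mc_n = 2e5, seed = 1)
  expect_lt(abs(v_const), 0.01)
  # optimal rule: xi * E|X'beta_opt| with X'beta_opt ~ N(0, 4)
  v_opt <- oracle_value(sc, sc$beta_opt, mc_n = 2e5, seed = 2)
  expect_equal(v_opt, 0.7 * 2 * sqrt(2 / pi), tolerance = 0.01)
  # sign-flipped rule: minus the Delta term of the optimal rule
  v_neg <- oracle_value(sc, -sc$beta_opt, mc_n = 2e5, seed = 3)
  expect_equal(v_neg, -0.7 * 2 * sqrt(2 / pi), tolerance = 0.01)
  # the reduced 5-deviate path agrees with the full-design function path
  v_fn <- oracle_value(sc, function(x) ifelse(drop(x %*% sc$beta_opt) >= 0, 1, -1),
                       mc_n = 2e5, seed = 4)
  expect_equal(v_fn, v_opt, tolerance = 0.015)
})

test_that("no rule beats the optimal rule", {
  sc <- itr_scenario("I", n = 100, p = 10, xi = 0.7)
  v_opt <- oracle_value(sc, sc$beta_opt, mc_n = 1e5, seed = 5)
  set.seed(11)
  for (r in 1:5) {
    beta <- rnorm(10)
    v <- oracle_value(sc, beta, mc_n = 1e5, seed = 5 + r)
    expect_lte(v, v_opt + 3 * 1.5 / sqrt(1e5))
  }
  sc2 <- itr_scenario("II", n = 100, p = 10, xi = 0.7)
  v_opt2 <- oracle_value(sc2, sc2$beta_opt, mc_n = 1e5, seed = 6)
  v_rand <- oracle_value(sc2, c(0, 1, 1, -1, rep(0.5, 6)), mc_n = 1e5, seed = 7)
  expect_lte(v_rand, v_opt2 + 3 * 6 / sqrt(1e5))
})
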