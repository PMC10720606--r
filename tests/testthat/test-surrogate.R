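test_that("logistic surrogate derivatives are exact and stable", {
  sg <- logistic_surrogate()
  expect_equal(sg$phi(0), log(2))
  expect_equal(sg$dphi(0), -0.5)
  expect_equal(sg$ddphi(0), 0.25)
  # phi'' equals the derivative of phi', checked by central finite differences
  eps <- 1e-5
  for (t in c(-3, -1, 0, 1, 3)) {
    fd <- (sg$dphi(t + eps) - sg$dphi(t - eps)) / (2 * eps)
    expect_equal(sg$ddphi(t), fd, tolerance = 1e-6)
  }
  # monotone decay to zero for large t, no overflow at extreme arguments
  ts <- c(5, 10, 20, 800)
  expect_true(all(diff(sg$phi(ts)) < 0) && all(is.finite(sg$phi(c(-800, 800)))))
  expect_equal(sg$phi(800), 0, tolerance = 1e-300)
  expect_equal(sg$phi(-800), 800)
  expect_true(all(abs(sg$dphi(ts)) < sg$dphi(0) * -1))
  expect_equal(sg$ddphi(800), 0)
})

test_that("penalized surrogate solver satisfies exact special cases", {
  set.seed(21)
  n <- 60
  x <- matrix(rnorm(n * 4), n, 4)
  op <- abs(rnorm(n, 1.5)); om <- abs(rnorm(n, 1))
  # lambda above the sup-norm of the gradient at zero forces beta = 0
  g0 <- abs(colMeans(-0.5 * (op - om) * x))
  fit <- penalized_surrogate(x, op, om, lambda = max(g0) * 1.05,
                             standardize = FALSE)
  expect_identical(unname(fit$beta), rep(0, 4))
  expect_true(fit$converged)
  # symmetric two-row problem has the symmetric solution beta = 0
  fs <- penalized_surrogate(matrix(c(1, -1), 2, 1), c(1, 1), c(1, 1), 0.01,
                            standardize = FALSE)
  expect_equal(unname(fs$beta), 0)
  # descent: the solution is no worse than the origin
  fit2 <- penalized_surrogate(x, op, om, 0.02, standardize = FALSE)
  expect_lte(fit2$objective, surr_obj_ref(x, op, om, rep(0, 4), 0.02) + 1e-10)
  expect_error(penalized_surrogate(x, op, om, -0.1), "nonnegative")
  expect_error(penalized_surrogate(x, -op, om, 0.1), "nonnegative")
})

test_that("solver agrees with an independent convex-optimizer oracle", {
  set.seed(22)
  n <- 60; p <- 3
  x <- matrix(rnorm(n * p), n, p)
  pr <- plogis(drop(x %*% c(1.5, -1, 0)))
  op <- abs(rnorm(n, 2)) * pr
  om <- abs(rnorm(n, 2)) * (1 - pr)
  fit <- penalized_surrogate(x, op, om, 0.05, standardize = FALSE)
  b_or <- oracle_surrogate(x, op, om, 0.05)
  expect_equal(fit$objective, surr_obj_ref(x, op, om, b_or, 0.05),
               tolerance = 1e-6)
  expect_equal(unname(fit$beta), b_or, tolerance = 1e-4)
  expect_lte(fit$kkt, 1e-6)
})

test_that("regularization path is monotone in support size and warm-started", {
  set.seed(23)
  n <- 150; p <- 20
  x <- matrix(rnorm(n * p), n, p)
  eta <- drop(x[, 1:3] %*% c(1, -1, 0.5))
  op <- abs(rnorm(n, 1)) * plogis(eta)
  om <- abs(rnorm(n, 1)) * plogis(-eta)
  grid <- pearlitr:::lambda_grid(n, p, 25)
  path <- penalized_surrogate(x, op, om, grid, standardize = FALSE)
  nz <- colSums(path$beta != 0)
  # grid is descending in lambda, so support sizes are non-decreasing
  expect_true(all(diff(nz) >= 0))
  expect_true(all(path$converged))
})

test_that("standardization solves the equivalent rescaled problem", {
  set.seed(24)
  n <- 80; p <- 5
  x <- matrix(rnorm(n * p), n, p) %*% diag(c(4, 2, 1, 0.5, 0.2))
  op <- abs(rnorm(n)); om <- abs(rnorm(n))
  f1 <- penalized_surrogate(x, op, om, 0.03, standardize = TRUE)
  scl <- sqrt(colMeans(x^2))
  f2 <- penalized_surrogate(sweep(x, 2, scl, "/"), op, om, 0.03,
                            standardize = FALSE)
  expect_equal(unname(f1$beta), unname(f2$beta / scl), tolerance = 1e-6)
  expect_equal(f1$objective, f2$objective, tolerance = 1e-8)
})

test_that("cross-validated penalty selection honours its contract", {
  set.seed(25)
  # singleton grid: no choice
  x <- matrix(rnorm(200), 50, 4)
  sl <- select_lambda(x, abs(rnorm(50)), abs(rnorm(50)), grid = 0.07)
  expect_equal(sl$lambda, 0.07)
  # returned value is always a grid member
  op <- abs(rnorm(50)); om <- abs(rnorm(50))
  sl2 <- select_lambda(x, op, om, grid_size = 10, seed = 1)
  expect_true(sl2$lambda %in% sl2$grid)
  # with strong signal, CV rejects a trivializing penalty
  sc <- itr_scenario("I", n = 1500, p = 15, xi = 0.7, seed = 26)
  dat <- sim_itr(sc)
  orc <- oracle_nuisances(sc)
  w <- aipw_weights(dat$y, dat$a, orc$pi(dat$x), orc$q(dat$x, 1), orc$q(dat$x, -1))
  big <- 10  # forces beta = 0
  sl3 <- select_lambda(dat$x, w$omega_plus, w$omega_minus,
                       grid = c(big, 0.05), seed = 2)
  expect_equal(sl3$lambda, 0.05)
})

test_that("degenerate all-zero weights give the zero rule", {
  x <- matrix(rnorm(80), 20, 4)
  fit <- penalized_surrogate(x, rep(0, 20), rep(0, 20), 0.1)
  expect_identical(unname(fit$beta), rep(0, 4))
  expect_true(isTRUE(fit$degenerate))
})
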