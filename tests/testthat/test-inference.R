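# a small cross-fitted rule with oracle nuisances, reused across blocks
infer_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    sc <- itr_scenario("I", n = 240, p = 6, xi = 0.7, seed = 51)
    dat <- sim_itr(sc)
    orc <- oracle_nuisances(sc)
    fit <- pearl(dat$x, dat$a, dat$y, K = 2, propensity = orc$pi,
                 outcome = orc$q, trim = NULL, lambda = 0.05, seed = 51)
    cache <<- list(sc = sc, dat = dat, fit = fit)
    cache
  }
})

test_that("fold score matches a direct evaluation of its definition", {
  fx <- infer_fixture()
  fit <- fx$fit
  res <- decor_score(fit, k = 1, j = 5, lambda_tilde = 0.03)
  # straight-line reimplementation from the stored fold pieces
  fold <- fit$fold[[1]]
  xk <- fit$x[fold$index, ]
  op <- fold$weights$omega_plus; om <- fold$weights$omega_minus
  beta_null <- replace(fold$beta, 5, 0)
  dphi <- function(t) -1 / (1 + exp(t))
  ddphi <- function(t) exp(t) / (1 + exp(t))^2
  eta <- drop(xk %*% fold$beta)
  h <- op * ddphi(eta) + om * ddphi(-eta)
  resid <- xk[, 5] - drop(xk[, -5] %*% res$w_hat)
  tn <- drop(xk %*% beta_null)
  S_ref <- mean((op * dphi(tn) - om * dphi(-tn)) * resid)
  I_ref <- mean(h * xk[, 5] * resid)
  S1_ref <- mean((op * dphi(eta) - om * dphi(-eta)) * resid)
  expect_equal(res$score, S_ref, tolerance = 1e-10)
  expect_equal(res$info, I_ref, tolerance = 1e-10)
  expect_equal(res$score_onestep, S1_ref, tolerance = 1e-10)
})

test_that("an overwhelming projection penalty reduces to the plain score", {
  fx <- infer_fixture()
  fit <- fx$fit
  res <- decor_score(fit, k = 2, j = 6, lambda_tilde = 1e5)
  expect_identical(unname(res$w_hat), rep(0, 5))
  fold <- fit$fold[[2]]
  xk <- fit$x[fold$index, ]
  op <- fold$weights$omega_plus; om <- fold$weights$omega_minus
  tn <- drop(xk %*% replace(fold$beta, 6, 0))
  dphi <- function(t) -1 / (1 + exp(t))
  expect_equal(res$score, mean((op * dphi(tn) - om * dphi(-tn)) * xk[, 6]),
               tolerance = 1e-12)
})

test_that("a perfectly predictable coordinate yields vanishing score and information", {
  fx <- infer_fixture()
  dat <- fx$dat
  orc <- oracle_nuisances(fx$sc)
  xdup <- cbind(dat$x, dat$x[, 5])
  colnames(xdup) <- paste0("x", 1:7)
  fit <- pearl(xdup, dat$a, dat$y, K = 2, propensity = function(nx) orc$pi(nx),
               outcome = function(nx, arm) orc$q(nx, arm), trim = NULL,
               lambda = 0.05, seed = 52)
  res <- decor_score(fit, k = 1, j = 5, lambda_tilde = 1e-4)
  expect_lt(abs(res$score), 1e-3)
  expect_lt(abs(res$info), 1e-3)
})

test_that("pooled statistics are exact arithmetic means of fold quantities", {
  fx <- infer_fixture()
  fit <- fx$fit
  lam <- 0.03
  tab <- pearl_infer(fit, coords = c(5, 6), lambda_tilde = lam, fdr = FALSE)
  for (row in 1:2) {
    j <- c(5, 6)[row]
    fr <- lapply(1:2, function(k) decor_score(fit, k, j, lambda_tilde = lam))
    S <- mean(sapply(fr, `[[`, "score"))
    sigma <- sqrt(mean(sapply(fr, function(r) mean(r$terms^2))))
    info_k <- sapply(fr, `[[`, "info")
    one_step <- mean(sapply(1:2, function(k)
      fit$fold[[k]]$beta[j] - fr[[k]]$score_onestep / info_k[k]))
    expect_equal(tab$statistic[row], sqrt(fit$n) * S / sigma, tolerance = 1e-12)
    expect_equal(tab$one_step[row], one_step, tolerance = 1e-12)
    # CI width is exactly twice the normal quantile times the standard error
    expect_equal(tab$conf_hi[row] - tab$conf_lo[row],
                 2 * qnorm(0.975) * sigma / (sqrt(fit$n) * abs(mean(info_k))),
                 tolerance = 1e-12)
  }
})

test_that("a constant zero outcome is reported as degenerate, not an error", {
  set.seed(53)
  x <- matrix(rnorm(120 * 5), 120, 5)
  a <- rep(c(-1, 1), 60)
  y <- rep(0, 120)
  fit <- pearl(x, a, y, K = 2, propensity = function(nx) rep(0.5, nrow(nx)),
               outcome = function(nx, arm) rep(0, nrow(nx)), trim = NULL,
               lambda = 0.05, seed = 53)
  expect_identical(unname(coef(fit)), rep(0, 5))
  tab <- pearl_infer(fit, coords = 1:2, fdr = FALSE)
  expect_true(all(tab$degenerate))
  expect_true(all(is.na(tab$p_value)))
})

test_that("q-values are the Benjamini-Hochberg step-up of the p-values", {
  fx <- infer_fixture()
  tab <- pearl_infer(fx$fit, coords = 3:6, lambda_tilde = 0.03, fdr = TRUE)
  expect_equal(tab$q_value, p.adjust(tab$p_value, "BH"))
  tab1 <- pearl_infer(fx$fit, coords = 5, lambda_tilde = 0.03, fdr = TRUE)
  expect_equal(tab1$q_value, tab1$p_value)
  # hand-computed step-up on a known p-value profile
  p <- c(0.001, 0.02, 0.8)
  q <- p.adjust(p, "BH")
  expect_identical(which(q <= 0.05), 1:2)
  expect_equal(q, c(0.003, 0.03, 0.8))
})

test_that("summary and confint wrap the inference table", {
  fx <- infer_fixture()
  sm <- summary(fx$fit, coords = c(1, 5), lambda_tilde = 0.03)
  expect_s3_class(sm, "summary.pearl")
  expect_equal(nrow(sm$table), 2)
  ci <- confint(fx$fit, parm = c(1, 5), lambda_tilde = 0.03)
  expect_equal(dim(ci), c(2, 2))
  expect_true(all(ci[, 1] < ci[, 2]))
  # signal coordinate excludes zero, null coordinate does not
  expect_true(ci["x1", 1] > 0)
  expect_true(ci["x5", 1] < 0 && ci["x5", 2] > 0)
})
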