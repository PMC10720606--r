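#' Benchmark simulation scenarios for individualized treatment rules
#'
#' Defines one of two observational-data generating designs with a known
#' optimal linear treatment rule.  Covariates are independent standard
#' normal, `X ~ N(0, I_p)`, and the outcome follows
#' `Y = A * Delta(X) + S(X) + eps` with `eps ~ N(0, 1)`, where `Delta` is
#' half the treatment contrast and `S` the main effect:
#'
#' * Scenario `"I"`: `Delta(X) = xi * X'b_opt`, `S(X) = 0.4 * X'b_S`, and a
#'   logistic propensity `pi(1; X) = expit(0.4 * X'b_pi)`.
#' * Scenario `"II"`: `Delta(X) = (Phi(xi * X'b_opt) - 0.5) * Dtilde(X)` with
#'   `Dtilde(X) = 2 * (X1 + X2 + X3 + X4)^2 + 2 * xi`,
#'   `S(X) = exp(0.4 * X'b_S)`, and propensity
#'   `pi(1; X) = expit((X1^2 + X2^2 + X1 X2) / 4)`.
#'
#' The coefficient patterns are fixed by the design:
#' `b_opt = (1, 1, -1, -1, 0, ...)`, `b_S = (-1, -1, 1, -1, 0, ...)`,
#' `b_pi = (1, -1, 0, ...)`.  In both scenarios the optimal rule is
#' `sgn(x'b_opt)` (in Scenario II because `Dtilde > 0`), with `sgn(0) = +1`.
#'
#' @param scenario `"I"` or `"II"`.
#' @param n number of observations to generate.
#' @param p number of covariates; at least 4.
#' @param xi treatment-effect magnitude, in `[0.1, 1]`.
#' @param seed optional integer seed stored with the design and used by
#'   [sim_itr()] unless overridden.
#' @return An object of class `"itr_scenario"`.
#' @seealso [sim_itr()], [oracle_rule()], [oracle_value()]
#' @examples
#' sc <- itr_scenario("I", n = 200, p = 10, xi = 0.7, seed = 1)
#' dat <- sim_itr(sc)
#' table(dat$a)
#' @export
itr_scenario <- function(scenario = c("I", "II"), n, p, xi = 0.7, seed = NULL) {
  scenario <- match.arg(scenario)
  check_scalar(n, "n", lo = 1, integer = TRUE)
  check_scalar(p, "p", lo = 4, integer = TRUE)
  check_scalar(xi, "xi", lo = 0.1, hi = 1)
  if (!is.null(seed)) check_scalar(seed, "seed", integer = TRUE)
  beta_opt <- c(1, 1, -1, -1, rep(0, p - 4))
  beta_s <- c(-1, -1, 1, -1, rep(0, p - 4))
  beta_pi <- c(1, -1, rep(0, p - 2))
  structure(list(scenario = scenario, n = as.integer(n), p = as.integer(p),
                 xi = xi, seed = seed, beta_opt = beta_opt,
                 beta_s = beta_s, beta_pi = beta_pi),
            class = "itr_scenario")
}

#' @export
#' @method print itr_scenario
print.itr_scenario <- function(x, ...) {
  cat(sprintf("ITR simulation scenario %s: n = %d, p = %d, xi = %.3g\n",
              x$scenario, x$n, x$p, x$xi))
  invisible(x)
}

# Closed-form design functions.  All depend on the first four covariate
# columns only (plus linear combinations handled by callers), so they accept
# any matrix with >= 4 columns.
scenario_fns <- function(spec) {
  xi <- spec$xi
  if (spec$scenario == "I") {
    list(
      delta = function(x) xi * (x[, 1] + x[, 2] - x[, 3] - x[, 4]),
      smean = function(x) 0.4 * (-x[, 1] - x[, 2] + x[, 3] - x[, 4]),
      pi1 = function(x) plogis(0.4 * (x[, 1] - x[, 2]))
    )
  } else {
    list(
      delta = function(x) {
        u <- x[, 1] + x[, 2] - x[, 3] - x[, 4]
        (pnorm(xi * u) - 0.5) * (2 * (x[, 1] + x[, 2] + x[, 3] + x[, 4])^2 + 2 * xi)
      },
      smean = function(x) exp(0.4 * (-x[, 1] - x[, 2] + x[, 3] - x[, 4])),
      pi1 = function(x) plogis((x[, 1]^2 + x[, 2]^2 + x[, 1] * x[, 2]) / 4)
    )
  }
}

#' Construct a validated (X, A, Y) dataset
#'
#' @param x numeric covariate matrix.
#' @param a treatment vector coded in `{-1, 1}` (or `{0, 1}`, mapped with
#'   `0 -> -1`).
#' @param y numeric outcome vector; larger values are better.
#' @return An object of class `"itr_data"`: a list with elements `x`, `a`,
#'   `y` and `column_names`.
#' @export
itr_data <- function(x, a, y) {
  x <- as_matrix_x(x)
  a <- as_treatment(a)
  if (!is.numeric(y)) stop("'y' must be numeric", call. = FALSE)
  y <- as.numeric(y)
  n <- nrow(x)
  if (length(a) != n || length(y) != n)
    stop("'x', 'a' and 'y' must have matching lengths", call. = FALSE)
  if (anyNA(x) || !all(is.finite(x)))
    stop("'x' contains missing or non-finite values", call. = FALSE)
  if (anyNA(y) || !all(is.finite(y)))
    stop("'y' contains missing or non-finite values", call. = FALSE)
  structure(list(x = x, a = a, y = y, column_names = colnames(x)),
            class = "itr_data")
}

#' @export
#' @method print itr_data
print.itr_data <- function(x, ...) {
  cat(sprintf("ITR dataset: n = %d, p = %d; treatment split %d / %d (A = -1 / +1)\n",
              nrow(x$x), ncol(x$x), sum(x$a == -1), sum(x$a == 1)))
  invisible(x)
}

#' @export
as.data.frame.itr_data <- function(x, ...) {
  data.frame(y = x$y, a = x$a, x$x, check.names = FALSE)
}

#' Simulate a dataset from a benchmark scenario
#'
#' Draws `X ~ N(0, I_p)`, assigns `A = +1` with probability `pi(1; X)`, and
#' generates `Y = A * Delta(X) + S(X) + N(0, 1)` noise according to the
#' design in `spec`.
#'
#' @param spec an [itr_scenario()] object.
#' @param seed integer seed; defaults to the seed stored in `spec`.  The
#'   caller's RNG state is left untouched when a seed is supplied.
#' @return An [itr_data()] object.
#' @export
sim_itr <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "itr_scenario"))
  fns <- scenario_fns(spec)
  with_seed(seed, {
    x <- matrix(rnorm(spec$n * spec$p), spec$n, spec$p,
                dimnames = list(NULL, paste0("x", seq_len(spec$p))))
    pi1 <- fns$pi1(x)
    a <- ifelse(runif(spec$n) < pi1, 1, -1)
    y <- a * fns$delta(x) + fns$smean(x) + rnorm(spec$n)
    itr_data(x, a, y)
  })
}

#' True optimal rule of a benchmark scenario
#'
#' Returns `sgn(x'b_opt)` with `sgn(0) = +1`; this is the optimal decision in
#' both scenarios because the treatment contrast is strictly increasing in
#' `x'b_opt` (Scenario II has a positive modulating factor).
#'
#' @param spec an [itr_scenario()] object.
#' @param x a single covariate vector of length `p`, or an `n x p` matrix.
#' @return `+1` / `-1` decisions (one per row of `x`).
#' @export
oracle_rule <- function(spec, x) {
  stopifnot(inherits(spec, "itr_scenario"))
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != spec$p)
    stop(sprintf("expected %d covariates, got %d", spec$p, ncol(x)), call. = FALSE)
  sgn(drop(x %*% spec$beta_opt))
}

#' Monte-Carlo value of a treatment rule under a benchmark scenario
#'
#' Approximates `V(D) = E[Delta(X) D(X) + S(X)]` (the mean outcome if rule
#' `D` were applied; noise integrates to zero) by averaging the noise-free
#' conditional mean over `mc_n` fresh draws.
#'
#' A rule given as a numeric coefficient vector `beta` (decision
#' `sgn(x'beta)`) uses an exact dimension reduction: `Delta`, `S` and
#' `x'beta` depend on `X` only through `(X1, ..., X4, x'beta)`, whose joint
#' law is known, so only five normal deviates per draw are needed.  A rule
#' given as a function of the full covariate vector is evaluated on chunked
#' draws of the complete design.
#'
#' @param spec an [itr_scenario()] object.
#' @param rule a numeric vector of length `p` (linear rule coefficients) or
#'   a function mapping an `m x p` matrix to decisions in `{-1, +1}`.
#' @param mc_n Monte-Carlo sample size (1e5 or more recommended).
#' @param seed optional integer seed.
#' @param chunk_size draws per block for function-valued rules.
#' @return The Monte-Carlo estimate of the value (a scalar).
#' @examples
#' sc <- itr_scenario("I", n = 100, p = 10, xi = 0.7)
#' # optimal value ~ 0.7 * 2 * sqrt(2 / pi)
#' oracle_value(sc, sc$beta_opt, mc_n = 1e5, seed = 1)
#' @export
oracle_value <- function(spec, rule, mc_n = 1e5, seed = NULL, chunk_size = 1e5) {
  stopifnot(inherits(spec, "itr_scenario"))
  check_scalar(mc_n, "mc_n", lo = 1, integer = TRUE)
  fns <- scenario_fns(spec)
  with_seed(seed, {
    if (is.numeric(rule) && !is.function(rule)) {
      if (length(rule) != spec$p)
        stop("'rule' coefficient vector must have length p", call. = FALSE)
      x4 <- matrix(rnorm(mc_n * 4), mc_n, 4)
      rest <- sqrt(sum(rule[-(1:4)]^2))
      xb <- drop(x4 %*% rule[1:4]) + if (rest > 0) rest * rnorm(mc_n) else 0
      mean(fns$delta(x4) * sgn(xb) + fns$smean(x4))
    } else if (is.function(rule)) {
      total <- 0
      left <- as.integer(mc_n)
      while (left > 0L) {
        m <- min(left, as.integer(chunk_size))
        x <- matrix(rnorm(m * spec$p), m, spec$p)
        d <- rule(x)
        if (!all(d %in% c(-1, 1)))
          stop("'rule' must return decisions in {-1, +1}", call. = FALSE)
        total <- total + sum(fns$delta(x) * d + fns$smean(x))
        left <- left - m
      }
      total / mc_n
    } else stop("'rule' must be a coefficient vector or a function", call. = FALSE)
  })
}
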