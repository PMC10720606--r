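#' Single-split inference for the value of a treatment rule
#'
#' Splits the data into two halves.  The rule (unless supplied) and the
#' nuisance models are fitted on the first half; on the second half the
#' augmented inverse-probability weights are formed with the first-half
#' nuisances and the value of the rule is estimated by
#' `V_hat = En2[ W1 I{D = 1} + Wm1 I{D = -1} ]`, with the normal interval
#' `V_hat +/- z * sigma_V / sqrt(n2)` where
#' `sigma_V^2 = En2[(W_{D(X)} - V_hat)^2]`.
#'
#' @inheritParams pearl
#' @param level confidence level.
#' @param rule optional fixed rule: a coefficient vector of length `p`
#'   (decision `sgn(x'rule)`) or a function `f(newx)` returning decisions
#'   in `{-1, +1}`.  When `NULL` (default) a [pearl()] rule is fitted on
#'   the training half with its own internal cross-fitting.
#' @param seed optional integer seed governing the half-split and all
#'   downstream fitting.
#' @return An object of class `"pearl_value"`: list with `v_hat`,
#'   `sigma_v`, `se`, `ci`, `n1`, `n2`, `level` and (when fitted) the
#'   training-half `fit`.
#' @examples
#' sc <- itr_scenario("I", n = 600, p = 10, xi = 0.7, seed = 11)
#' dat <- sim_itr(sc)
#' value_ci(dat$x, dat$a, dat$y, propensity = "penalized_logistic",
#'          outcome = "penalized_linear", seed = 11)
#' @export
value_ci <- function(x, a, y, level = 0.95, K = 2,
                     propensity = c("screened_kernel", "penalized_logistic"),
                     outcome = c("screened_kernel", "penalized_linear"),
                     trim = c(0.1, 0.9), rule = NULL,
                     control = pearl_control(), seed = NULL) {
  dat <- itr_data(x, a, y)
  x <- dat$x; a <- dat$a; y <- dat$y
  n <- nrow(x)
  if (n < 4 * K) stop("need n >= 4K for the half-split procedure", call. = FALSE)
  if (!is.function(propensity)) propensity <- match.arg(propensity)
  if (!is.function(outcome)) outcome <- match.arg(outcome)
  check_scalar(level, "level", lo = 0.5, hi = 1 - 1e-12)
  with_seed(seed, {
    i1 <- sort(sample(n, n %/% 2))
    i2 <- setdiff(seq_len(n), i1)
    if (length(unique(a[i1])) < 2 || length(unique(a[i2])) < 2)
      stop("a treatment arm is missing in one half of the split", call. = FALSE)
    fit <- NULL
    d2 <- if (is.null(rule)) {
      fit <- pearl(x[i1, , drop = FALSE], a[i1], y[i1], K = K,
                   propensity = propensity, outcome = outcome, trim = trim,
                   control = control)
      predict(fit, x[i2, , drop = FALSE])
    } else if (is.numeric(rule) && !is.function(rule)) {
      if (length(rule) != ncol(x)) stop("'rule' must have length p", call. = FALSE)
      sgn(drop(x[i2, , drop = FALSE] %*% rule))
    } else if (is.function(rule)) {
      rule(x[i2, , drop = FALSE])
    } else stop("'rule' must be NULL, a coefficient vector, or a function",
                call. = FALSE)
    if (!all(d2 %in% c(-1, 1)))
      stop("rule decisions must lie in {-1, +1}", call. = FALSE)
    # nuisances for the inference half are (re)fitted on the whole training half
    pi_fn <- resolve_propensity(propensity, x[i1, , drop = FALSE], a[i1],
                                control$nuisance)
    q_fn <- resolve_outcome(outcome, x[i1, , drop = FALSE], a[i1], y[i1],
                            control$nuisance)
    x2 <- x[i2, , drop = FALSE]
    pi1 <- pi_fn(x2)
    if (!is.null(trim)) pi1 <- trim_propensity(pi1, trim[1], trim[2])
    wts <- aipw_weights(y[i2], a[i2], pi1, q_fn(x2, 1), q_fn(x2, -1))
    wd <- ifelse(d2 == 1, wts$w1, wts$wm1)
    n2 <- length(i2)
    v <- mean(wd)
    sigma_v <- sqrt(mean((wd - v)^2))
    se <- sigma_v / sqrt(n2)
    zq <- qnorm(1 - (1 - level) / 2)
    structure(list(v_hat = v, sigma_v = sigma_v, se = se,
                   ci = c(lower = v - zq * se, upper = v + zq * se),
                   n1 = length(i1), n2 = n2, level = level, fit = fit),
              class = "pearl_value")
  })
}

#' @export
#' @method print pearl_value
print.pearl_value <- function(x, digits = 4, ...) {
  cat(sprintf("Single-split value inference (n1 = %d training, n2 = %d inference)\n",
              x$n1, x$n2))
  cat(sprintf("  V_hat = %s, se = %s, %.0f%% CI [%s, %s]\n",
              signif(x$v_hat, digits), signif(x$se, digits), 100 * x$level,
              signif(x$ci[1], digits), signif(x$ci[2], digits)))
  invisible(x)
}
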