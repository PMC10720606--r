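#' Doubly robust AIPW weights and their sign decomposition
#'
#' Computes the augmented inverse-probability weights
#' \deqn{\hat W_a = \frac{Y I\{A = a\}}{\hat\pi(a; X)} -
#'   \frac{[I\{A = a\} - \hat\pi(a; X)]\, \hat Q(a; X)}{\hat\pi(a; X)}}
#' for `a = +1, -1`, together with the nonnegative decomposition
#' `Omega_plus = W1_+ + Wm1_-` and `Omega_minus = W1_- + Wm1_+` used as case
#' weights in the surrogate-loss classification problem (`Omega_plus`
#' encourages treating with `A = +1`, `Omega_minus` with `A = -1`).
#'
#' @param y outcome vector.
#' @param a treatment vector in `{-1, 1}`.
#' @param pi1 estimated propensity `P(A = 1 | X)`, strictly inside (0, 1);
#'   apply [trim_propensity()] first if needed.  `pi(-1; x) = 1 - pi1`.
#' @param q1,qm1 estimated outcome means `Q(1; x)` and `Q(-1; x)`.
#' @return An object of class `"aipw_weights"`: list with `w1`, `wm1`,
#'   `omega_plus`, `omega_minus`.
#' @export
aipw_weights <- function(y, a, pi1, q1, qm1) {
  a <- as_treatment(a)
  n <- length(y)
  stopifnot(length(a) == n, length(pi1) == n, length(q1) == n, length(qm1) == n)
  if (!all(is.finite(y)) || !all(is.finite(q1)) || !all(is.finite(qm1)))
    stop("outcome and outcome-model predictions must be finite", call. = FALSE)
  if (!all(is.finite(pi1)) || any(pi1 <= 0) || any(pi1 >= 1))
    stop("'pi1' must lie strictly inside (0, 1); trim extreme propensities first",
         call. = FALSE)
  i1 <- as.numeric(a == 1)
  im1 <- 1 - i1
  w1 <- y * i1 / pi1 - (i1 - pi1) * q1 / pi1
  wm1 <- y * im1 / (1 - pi1) - (im1 - (1 - pi1)) * qm1 / (1 - pi1)
  out <- omega_decompose(w1, wm1)
  structure(list(w1 = w1, wm1 = wm1,
                 omega_plus = out$omega_plus, omega_minus = out$omega_minus),
            class = "aipw_weights")
}

#' Positive/negative decomposition of a pair of AIPW weights
#'
#' @param w1,wm1 weight vectors for arms `+1` and `-1`.
#' @return list with nonnegative `omega_plus`, `omega_minus` satisfying
#'   `omega_plus - omega_minus == w1 - wm1` and
#'   `omega_plus + omega_minus == |w1| + |wm1|`.
#' @export
omega_decompose <- function(w1, wm1) {
  if (!all(is.finite(w1)) || !all(is.finite(wm1)))
    stop("weights must be finite", call. = FALSE)
  list(omega_plus = pmax(w1, 0) + pmax(-wm1, 0),
       omega_minus = pmax(-w1, 0) + pmax(wm1, 0))
}

#' Trim estimated propensity scores
#'
#' Clamps estimated propensities into `[lo, hi]` (defaults 0.1 and 0.9) to
#' guard against extreme inverse weights.  Idempotent.  Intended for
#' estimated propensities only, never for known randomization probabilities.
#'
#' @param pi1 vector of estimated propensities.
#' @param lo,hi trimming caps, `0 < lo < hi < 1`.
#' @export
trim_propensity <- function(pi1, lo = 0.1, hi = 0.9) {
  check_scalar(lo, "lo", lo = .Machine$double.eps, hi = 1 - .Machine$double.eps)
  check_scalar(hi, "hi", lo = .Machine$double.eps, hi = 1 - .Machine$double.eps)
  if (lo >= hi) stop("'lo' must be smaller than 'hi'", call. = FALSE)
  pmin(pmax(pi1, lo), hi)
}
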