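#' Control settings for [pearl()]
#'
#' @param solver a [solver_control()] list.
#' @param lambda list with `grid_size` and `cv_folds` for the penalty
#'   cross-validation of both the rule fit and the de-correlation
#'   regressions.
#' @param nuisance a [nuisance_control()] list.
#' @export
pearl_control <- function(solver = solver_control(),
                          lambda = list(grid_size = 50, cv_folds = 5),
                          nuisance = nuisance_control()) {
  list(solver = solver, lambda = lambda, nuisance = nuisance)
}

# resolve a propensity spec (method name or prediction function) on a
# training split; returns function(newx) -> pi1
resolve_propensity <- function(propensity, x, a, control) {
  if (is.function(propensity)) return(propensity)
  fit <- fit_propensity(x, a, method = propensity, control = control)
  function(newx) predict(fit, newx)
}

# resolve an outcome spec; returns function(newx, arm) -> Q(arm; newx)
resolve_outcome <- function(outcome, x, a, y, control) {
  if (is.function(outcome)) return(outcome)
  fit <- fit_outcome(x, a, y, method = outcome, control = control)
  function(newx, arm) predict(fit, newx, arm = arm)
}

#' Penalized EARL: doubly robust estimation of a linear treatment rule
#'
#' Fits a sparse linear individualized treatment rule
#' `D(x) = sgn(x'beta)` from observational data by cross-fitted, penalized
#' efficient augmentation and relaxation learning.  The data are split into
#' `K` folds; on each fold's complement the propensity `pi(1; x)` and the
#' per-arm outcome means `Q(a; x)` are estimated, the augmented
#' inverse-probability weights and their sign decomposition
#' `(Omega_plus, Omega_minus)` are evaluated on the held-out fold, and the
#' fold coefficient vector solves the l1-penalized weighted logistic
#' surrogate problem (see [penalized_surrogate()]) with its own
#' cross-validated penalty.  The reported coefficients are the arithmetic
#' mean of the `K` fold estimates.  Consistency requires only one of the
#' two nuisance models to be correct (double robustness).
#'
#' @param x covariate matrix (n x p).  No intercept is added; decision
#'   rules are linear through the origin.
#' @param a treatment vector coded `{-1, 1}` (or `{0, 1}` with `0 -> -1`).
#' @param y outcome vector, larger is better.
#' @param K number of cross-fitting folds (>= 2).
#' @param propensity `"screened_kernel"` (distance-correlation screening +
#'   kernel smoothing, the default), `"penalized_logistic"`, or a function
#'   `f(newx)` returning `P(A = 1 | X)` (e.g. a known randomization
#'   probability).
#' @param outcome `"screened_kernel"`, `"penalized_linear"`, or a function
#'   `f(newx, arm)` returning `Q(arm; newx)`.
#' @param trim length-2 caps applied to estimated propensities before
#'   weighting (default `c(0.1, 0.9)`); `NULL` disables trimming (use for
#'   known randomization probabilities).
#' @param lambda optional fixed penalty applied to every fold; `NULL`
#'   selects a penalty per fold by cross-validation.
#' @param control a [pearl_control()] list.
#' @param seed optional integer seed making the fold split, nuisance
#'   cross-validation and penalty selection reproducible.
#' @return An object of class `"pearl"` with components `coefficients`
#'   (pooled), `fold` (per-fold index set, nuisance predictions, weights,
#'   coefficients, penalty, solver diagnostics), `plan`, and the training
#'   data (retained for coordinate inference).
#' @seealso [pearl_infer()] for coefficient tests and confidence intervals,
#'   [value_ci()] for inference on the value of the rule.
#' @examples
#' sc <- itr_scenario("I", n = 400, p = 10, xi = 0.7, seed = 7)
#' dat <- sim_itr(sc)
#' fit <- pearl(dat$x, dat$a, dat$y, K = 2, propensity = "penalized_logistic",
#'              outcome = "penalized_linear", seed = 7)
#' coef(fit)
#' mean(predict(fit, dat$x) == oracle_rule(sc, dat$x))
#' @export
pearl <- function(x, a, y, K = 2,
                  propensity = c("screened_kernel", "penalized_logistic"),
                  outcome = c("screened_kernel", "penalized_linear"),
                  trim = c(0.1, 0.9), lambda = NULL,
                  control = pearl_control(), seed = NULL) {
  cl <- match.call()
  dat <- itr_data(x, a, y)
  x <- dat$x; a <- dat$a; y <- dat$y
  n <- nrow(x); p <- ncol(x)
  if (!is.function(propensity)) propensity <- match.arg(propensity)
  if (!is.function(outcome)) outcome <- match.arg(outcome)
  if (!is.null(trim)) {
    stopifnot(length(trim) == 2)
    if (!(trim[1] < trim[2])) stop("invalid 'trim' bounds", call. = FALSE)
  }
  with_seed(seed, {
    plan <- make_folds(n, K)
    folds <- vector("list", K)
    for (k in seq_len(K)) {
      te <- plan$folds[[k]]
      tr <- setdiff(seq_len(n), te)
      if (length(unique(a[tr])) < 2)
        stop(sprintf("fold %d: training complement contains a single treatment arm", k),
             call. = FALSE)
      pi_fn <- tryCatch(
        resolve_propensity(propensity, x[tr, , drop = FALSE], a[tr], control$nuisance),
        error = function(e) stop(sprintf("fold %d propensity fit failed: %s",
                                         k, conditionMessage(e)), call. = FALSE))
      q_fn <- tryCatch(
        resolve_outcome(outcome, x[tr, , drop = FALSE], a[tr], y[tr], control$nuisance),
        error = function(e) stop(sprintf("fold %d outcome fit failed: %s",
                                         k, conditionMessage(e)), call. = FALSE))
      xte <- x[te, , drop = FALSE]
      pi1 <- pi_fn(xte)
      if (!is.null(trim)) pi1 <- trim_propensity(pi1, trim[1], trim[2])
      q1 <- q_fn(xte, 1)
      qm1 <- q_fn(xte, -1)
      wts <- aipw_weights(y[te], a[te], pi1, q1, qm1)
      lam_k <- if (is.null(lambda)) {
        select_lambda(xte, wts$omega_plus, wts$omega_minus,
                      grid_size = control$lambda$grid_size,
                      cv_folds = control$lambda$cv_folds,
                      control = control$solver)$lambda
      } else lambda
      sfit <- penalized_surrogate(xte, wts$omega_plus, wts$omega_minus, lam_k,
                                  control = control$solver)
      folds[[k]] <- list(index = te, pi1 = pi1, q1 = q1, qm1 = qm1,
                         weights = wts, beta = sfit$beta, lambda = lam_k,
                         converged = sfit$converged, kkt = sfit$kkt,
                         iterations = sfit$iterations,
                         objective = sfit$objective)
    }
    beta <- rowMeans(vapply(folds, `[[`, numeric(p), "beta"))
    names(beta) <- colnames(x)
    structure(list(coefficients = beta, fold = folds, plan = plan,
                   K = as.integer(K), n = n, p = p, trim = trim,
                   propensity = if (is.function(propensity)) "user function" else propensity,
                   outcome = if (is.function(outcome)) "user function" else outcome,
                   lambda = vapply(folds, `[[`, numeric(1), "lambda"),
                   control = control, seed = seed, call = cl,
                   x = x, a = a, y = y),
              class = "pearl")
  })
}

#' @export
#' @method print pearl
print.pearl <- function(x, ...) {
  cat("Penalized EARL treatment rule\n")
  cat(sprintf("  n = %d, p = %d, K = %d folds; nuisances: propensity = %s, outcome = %s\n",
              x$n, x$p, x$K, x$propensity, x$outcome))
  cat(sprintf("  fold penalties: %s\n", paste(signif(x$lambda, 3), collapse = ", ")))
  nz <- which(x$coefficients != 0)
  cat(sprintf("  pooled coefficients: %d nonzero of %d\n", length(nz), x$p))
  if (length(nz)) {
    show <- nz[order(-abs(x$coefficients[nz]))]
    show <- head(show, 8)
    print(signif(x$coefficients[show], 3))
  }
  if (!all(vapply(x$fold, `[[`, logical(1), "converged")))
    cat("  warning: solver flagged non-convergence on at least one fold\n")
  invisible(x)
}

#' @export
coef.pearl <- function(object, ...) object$coefficients

#' Apply an estimated rule to new covariates
#'
#' @param object a fitted [pearl()] object.
#' @param newx covariate matrix with the same columns as the training data.
#' @param type `"rule"` for decisions `sgn(x'beta)` (with `sgn(0) = +1`),
#'   `"link"` for the linear score `x'beta`.
#' @param ... unused.
#' @export
predict.pearl <- function(object, newx, type = c("rule", "link"), ...) {
  type <- match.arg(type)
  if (is.vector(newx)) newx <- matrix(newx, nrow = 1)
  if (ncol(newx) != object$p)
    stop(sprintf("expected %d covariates, got %d", object$p, ncol(newx)),
         call. = FALSE)
  eta <- drop(newx %*% object$coefficients)
  if (type == "link") eta else sgn(eta)
}

#' @export
plot.pearl <- function(x, max_coef = 30, ...) {
  p <- x$p
  show <- if (p > max_coef) order(-abs(x$coefficients))[seq_len(max_coef)] else seq_len(p)
  show <- sort(show)
  bmat <- vapply(x$fold, `[[`, numeric(p), "beta")[show, , drop = FALSE]
  ylim <- range(0, bmat, x$coefficients[show])
  graphics::plot(seq_along(show), x$coefficients[show], pch = 19,
                 xaxt = "n", xlab = "coefficient", ylab = "estimate",
                 ylim = ylim, main = "Pooled and fold-wise rule coefficients", ...)
  graphics::axis(1, at = seq_along(show), labels = names(x$coefficients)[show],
                 las = 2, cex.axis = 0.7)
  for (k in seq_len(ncol(bmat)))
    graphics::points(seq_along(show), bmat[, k], pch = 1, col = "grey50")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
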