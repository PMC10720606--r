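#' Settings for nuisance-model estimation
#'
#' @param cv_folds folds for the internal penalty cross-validation.
#' @param nlambda length of the glmnet penalty path.
#' @param screen_d screening budget for the kernel methods; `NULL` means
#'   `floor(n / log(n))`.
#' @param min_per_arm minimum rows required in each treatment arm for
#'   outcome-model fitting.
#' @param clip propensity predictions are clipped into
#'   `[clip, 1 - clip]` so they stay strictly inside (0, 1) before any
#'   user-level trimming.
#' @export
nuisance_control <- function(cv_folds = 5, nlambda = 50, screen_d = NULL,
                             min_per_arm = 10, clip = 1e-6) {
  list(cv_folds = cv_folds, nlambda = nlambda, screen_d = screen_d,
       min_per_arm = min_per_arm, clip = clip)
}

screen_budget <- function(n, control) {
  d <- control$screen_d %||% max(1L, floor(n / log(n)))
  as.integer(d)
}

# rule-of-thumb bandwidth on standardized covariates
rot_bandwidth <- function(n, d_used) 1.06 * n^(-1 / (4 + d_used))

# screening + product-Gaussian-kernel smoother of `resp` on x[, idx]
kernel_smoother <- function(x, resp, idx) {
  xs <- x[, idx, drop = FALSE]
  ctr <- colMeans(xs)
  scl <- apply(xs, 2, sd)
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- scale(xs, center = ctr, scale = scl)
  h <- rot_bandwidth(nrow(xs), length(idx))
  force(resp)
  function(newx) {
    newx <- newx[, idx, drop = FALSE]
    newx <- scale(newx, center = ctr, scale = scl)
    drop(cpp_nw(xs, resp, newx, h))
  }
}

#' Fit a propensity model on a training split
#'
#' Either an l1-penalized logistic regression with penalty chosen by
#' cross-validation, or distance-correlation screening of the treatment on
#' the covariates followed by Nadaraya-Watson kernel smoothing of
#' `I{A = 1}` on the retained (standardized) coordinates with the
#' rule-of-thumb bandwidth `1.06 * n^(-1/(4 + d))`.
#'
#' @param x covariate matrix (training rows only).
#' @param a treatment vector in `{-1, 1}`; both arms must be present.
#' @param method `"penalized_logistic"` or `"screened_kernel"`.
#' @param control a [nuisance_control()] list.
#' @return An object of class `"nuisance_fit"`; `predict(fit, newx)` returns
#'   estimated `P(A = 1 | X = newx)` in (0, 1) (untrimmed).
#' @export
fit_propensity <- function(x, a, method = c("penalized_logistic", "screened_kernel"),
                           control = nuisance_control()) {
  method <- match.arg(method)
  x <- as_matrix_x(x)
  a <- as_treatment(a)
  if (length(unique(a)) < 2)
    stop("both treatment arms must be present in the training data", call. = FALSE)
  clip <- control$clip
  if (method == "penalized_logistic") {
    cv <- glmnet::cv.glmnet(x, as.numeric(a == 1), family = "binomial",
                            nfolds = control$cv_folds, nlambda = control$nlambda)
    fn <- function(newx) {
      p <- drop(predict(cv, newx = newx, s = "lambda.min", type = "response"))
      pmin(pmax(p, clip), 1 - clip)
    }
    model <- cv
    screened <- NULL
  } else {
    idx <- screen_dcor(x, as.numeric(a == 1), screen_budget(nrow(x), control))
    sm <- kernel_smoother(x, as.numeric(a == 1), idx)
    fn <- function(newx) pmin(pmax(sm(newx), clip), 1 - clip)
    model <- NULL
    screened <- idx
  }
  structure(list(predict = fn, method = method, screened = screened,
                 model = model, n_train = nrow(x)),
            class = "nuisance_fit")
}

#' Fit per-arm outcome models on a training split
#'
#' Fits `Q(a; x) = E(Y | X = x, A = a)` separately within each treatment
#' arm, either by l1-penalized least squares (penalty by cross-validation)
#' or by distance-correlation screening of the outcome on the covariates
#' followed by kernel smoothing.  An arm with (numerically) constant outcome
#' gets the constant predictor.
#'
#' @param x covariate matrix (training rows only).
#' @param a treatment vector in `{-1, 1}`.
#' @param y outcome vector.
#' @param method `"penalized_linear"` or `"screened_kernel"`.
#' @param control a [nuisance_control()] list.
#' @return An object of class `"outcome_fit"`; `predict(fit, newx, arm)`
#'   returns `Q(arm; newx)` for `arm` in `{-1, 1}`.
#' @export
fit_outcome <- function(x, a, y, method = c("penalized_linear", "screened_kernel"),
                        control = nuisance_control()) {
  method <- match.arg(method)
  x <- as_matrix_x(x)
  a <- as_treatment(a)
  stopifnot(length(y) == nrow(x), length(a) == nrow(x))
  fit_arm <- function(arm) {
    rows <- which(a == arm)
    if (length(rows) < control$min_per_arm)
      stop(sprintf("arm %+d has %d rows; need at least %d", arm, length(rows),
                   control$min_per_arm), call. = FALSE)
    xa <- x[rows, , drop = FALSE]
    ya <- y[rows]
    if (sd(ya) < 1e-12) {
      cst <- mean(ya)
      return(function(newx) rep(cst, nrow(newx)))
    }
    if (method == "penalized_linear") {
      cv <- glmnet::cv.glmnet(xa, ya, family = "gaussian",
                              nfolds = control$cv_folds, nlambda = control$nlambda)
      function(newx) drop(predict(cv, newx = newx, s = "lambda.min"))
    } else {
      idx <- screen_dcor(xa, ya, screen_budget(length(rows), control))
      kernel_smoother(xa, ya, idx)
    }
  }
  structure(list(q1 = fit_arm(1), qm1 = fit_arm(-1), method = method,
                 n_train = nrow(x)),
            class = "outcome_fit")
}

#' @export
predict.nuisance_fit <- function(object, newx, ...) {
  object$predict(as_matrix_x(newx))
}

#' @param arm treatment arm, `1` or `-1`.
#' @rdname fit_outcome
#' @export
predict.outcome_fit <- function(object, newx, arm, ...) {
  newx <- as_matrix_x(newx)
  if (arm == 1) object$q1(newx) else object$qm1(newx)
}
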