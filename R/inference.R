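#' Fold-level de-correlated score for one coordinate
#'
#' On fold `k` of a fitted rule, computes the de-correlation projection
#' `w_hat` (weighted lasso of `X_j` on `X_{-j}` with weights
#' `d2 l_phi(beta^(k))`), the de-correlated score at the null-restricted
#' coefficients (`beta^(k)` with coordinate `j` set to 0), the score at
#' `beta^(k)` itself (used by the one-step correction), and the partial
#' information `I_{j|-j} = En[d2 l_phi(beta^(k)) X_j (X_j - X_{-j}'w)]`.
#'
#' @param fit a [pearl()] object.
#' @param k fold index.
#' @param j coordinate index.
#' @param lambda_tilde penalty for the de-correlation lasso; `NULL` selects
#'   it by cross-validation within the fold.
#' @param control a [pearl_control()] list (defaults to the fit's).
#' @return list with `w_hat`, `score` (at the null-restricted
#'   coefficients), `score_onestep` (at `beta^(k)`), `info`, `terms`
#'   (per-row de-correlated score terms entering the variance estimate),
#'   and `lambda_tilde`.
#' @export
decor_score <- function(fit, k, j, lambda_tilde = NULL, control = NULL) {
  stopifnot(inherits(fit, "pearl"))
  control <- control %||% fit$control
  check_scalar(k, "k", lo = 1, hi = fit$K, integer = TRUE)
  check_scalar(j, "j", lo = 1, hi = fit$p, integer = TRUE)
  fold <- fit$fold[[k]]
  xk <- fit$x[fold$index, , drop = FALSE]
  op <- fold$weights$omega_plus
  om <- fold$weights$omega_minus
  beta <- fold$beta
  sg <- logistic_surrogate()
  eta <- drop(xk %*% beta)
  h <- op * sg$ddphi(eta) + om * sg$ddphi(-eta)
  if (sum(h) <= 0) {
    # all case weights vanish: every score term is exactly zero and the
    # coordinate is reported as degenerate downstream
    zero <- rep(0, nrow(xk))
    return(list(w_hat = setNames(rep(0, fit$p - 1), colnames(xk)[-j]),
                score = 0, score_onestep = 0, info = 0, terms = zero,
                lambda_tilde = NA_real_))
  }
  if (is.null(lambda_tilde))
    lambda_tilde <- select_lambda_tilde(xk, j, h,
                                        grid_size = control$lambda$grid_size,
                                        cv_folds = control$lambda$cv_folds,
                                        control = control$solver)$lambda
  dfit <- tryCatch(
    decorrelation_lasso(xk, j, h, lambda_tilde, control = control$solver),
    error = function(e) stop(sprintf("de-correlation lasso failed (fold %d, coordinate %d): %s",
                                     k, j, conditionMessage(e)), call. = FALSE))
  resid <- xk[, j] - drop(xk[, -j, drop = FALSE] %*% dfit$w)
  eta_null <- eta - xk[, j] * beta[j]
  grad_null <- op * sg$dphi(eta_null) - om * sg$dphi(-eta_null)
  grad_full <- op * sg$dphi(eta) - om * sg$dphi(-eta)
  terms <- grad_null * resid
  list(w_hat = dfit$w, score = mean(terms),
       score_onestep = mean(grad_full * resid),
       info = mean(h * xk[, j] * resid), terms = terms,
       lambda_tilde = lambda_tilde)
}

#' Split-and-pooled de-correlated score inference for rule coefficients
#'
#' For each requested coordinate, pools the fold-wise de-correlated scores
#' `S_j = K^{-1} sum_k S_j^(k)` and tests `H0: beta_j = 0` against the
#' normal reference `sqrt(n) S_j / sigma_hat_j`, where `sigma_hat_j^2` is
#' the pooled empirical second moment of the per-row de-correlated score
#' terms.  Also forms the pooled one-step (de-biased) estimator
#' `beta_tilde_j = K^{-1} sum_k [beta_j^(k) - S_j^(k)(beta^(k)) / I_{j|-j}^(k)]`
#' and its normal confidence interval
#' `beta_tilde_j +/- z_{1-alpha/2} sigma_hat_j / (sqrt(n) I_{j|-j})`.
#'
#' @param object a [pearl()] fit.
#' @param coords coordinates to test; defaults to the nonzero pooled
#'   coefficients (or the first `min(p, 8)` if none).
#' @param level confidence level (default 0.95).
#' @param lambda_tilde optional fixed de-correlation penalty (otherwise
#'   cross-validated per fold and coordinate).
#' @param fdr append Benjamini-Hochberg adjusted q-values.
#' @param seed optional seed for the penalty cross-validation.
#' @param control override the fit's [pearl_control()] settings.
#' @return A data frame of class `"pearl_infer"` with one row per
#'   coordinate: pooled `estimate`, one-step estimate `one_step`, standard
#'   error `se`, z `statistic`, `p_value`, optional `q_value`, confidence
#'   bounds, and flags `degenerate` (zero score variance) and `unstable`
#'   (near-zero fold information).
#' @export
pearl_infer <- function(object, coords = NULL, level = 0.95,
                        lambda_tilde = NULL, fdr = TRUE, seed = NULL,
                        control = NULL) {
  stopifnot(inherits(object, "pearl"))
  control <- control %||% object$control
  check_scalar(level, "level", lo = 0.5, hi = 1 - 1e-12)
  if (is.null(coords)) {
    coords <- which(object$coefficients != 0)
    if (!length(coords)) coords <- seq_len(min(object$p, 8))
  }
  coords <- as.integer(coords)
  if (!length(coords) || any(coords < 1 | coords > object$p))
    stop("'coords' must be a nonempty set of coordinate indices", call. = FALSE)
  n <- object$n
  K <- object$K
  zq <- qnorm(1 - (1 - level) / 2)
  with_seed(seed, {
    rows <- lapply(coords, function(j) {
      fold_res <- lapply(seq_len(K), function(k)
        decor_score(object, k, j, lambda_tilde = lambda_tilde, control = control))
      S <- mean(vapply(fold_res, `[[`, numeric(1), "score"))
      info_k <- vapply(fold_res, `[[`, numeric(1), "info")
      info <- mean(info_k)
      sigma2 <- mean(vapply(fold_res, function(r) mean(r$terms^2), numeric(1)))
      beta_k <- vapply(seq_len(K), function(k) object$fold[[k]]$beta[j], numeric(1))
      unstable <- any(abs(info_k) < 1e-8)
      degenerate <- sigma2 <= 0
      one_step <- if (unstable) NA_real_ else
        mean(beta_k - vapply(fold_res, `[[`, numeric(1), "score_onestep") / info_k)
      z <- if (degenerate) NA_real_ else sqrt(n) * S / sqrt(sigma2)
      se <- if (degenerate || unstable) NA_real_ else sqrt(sigma2) / (sqrt(n) * abs(info))
      data.frame(term = colnames(object$x)[j], j = j,
                 estimate = unname(object$coefficients[j]),
                 one_step = one_step, se = se, statistic = z,
                 p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
                 conf_lo = one_step - zq * se, conf_hi = one_step + zq * se,
                 degenerate = degenerate, unstable = unstable,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (fdr) {
      out$q_value <- p.adjust(out$p_value, method = "BH")
      out <- out[, c("term", "j", "estimate", "one_step", "se", "statistic",
                     "p_value", "q_value", "conf_lo", "conf_hi",
                     "degenerate", "unstable")]
    }
    rownames(out) <- NULL
    structure(out, class = c("pearl_infer", "data.frame"),
              level = level, n = n, K = K)
  })
}

#' @export
#' @method print pearl_infer
print.pearl_infer <- function(x, digits = 4, ...) {
  cat(sprintf("De-correlated score inference (K = %d folds, n = %d, %.0f%% CIs)\n",
              attr(x, "K"), attr(x, "n"), 100 * attr(x, "level")))
  df <- as.data.frame(x)
  if (any(df$degenerate)) cat("note: coordinates with zero score variance are marked degenerate\n")
  if (any(df$unstable)) cat("note: coordinates with near-zero information are marked unstable\n")
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method summary pearl
summary.pearl <- function(object, coords = NULL, level = 0.95, fdr = TRUE,
                          seed = NULL, ...) {
  tab <- pearl_infer(object, coords = coords, level = level, fdr = fdr,
                     seed = seed)
  structure(list(fit = object, table = tab), class = "summary.pearl")
}

#' @export
#' @method print summary.pearl
print.summary.pearl <- function(x, ...) {
  print(x$fit)
  cat("\n")
  print(x$table, ...)
  invisible(x)
}

#' @export
confint.pearl <- function(object, parm = NULL, level = 0.95, ...) {
  tab <- pearl_infer(object, coords = parm, level = level, fdr = FALSE, ...)
  out <- as.matrix(tab[, c("conf_lo", "conf_hi")])
  a <- (1 - level) / 2
  colnames(out) <- paste(format(100 * c(a, 1 - a), trim = TRUE), "%")
  rownames(out) <- tab$term
  out
}
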