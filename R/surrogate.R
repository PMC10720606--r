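#' Logistic surrogate loss and its derivatives
#'
#' The smooth strictly convex surrogate `phi(t) = log(1 + exp(-t))` used in
#' place of the 0-1 loss, with `phi'(t) = -1 / (1 + exp(t))` and
#' `phi''(t) = exp(t) / (1 + exp(t))^2`.  All three are evaluated in
#' overflow-safe form.
#'
#' @return list of vectorized functions `phi`, `dphi`, `ddphi`.
#' @export
logistic_surrogate <- function() {
  list(
    phi = function(t) ifelse(t > 0, log1p(exp(-t)), -t + log1p(exp(t))),
    dphi = function(t) -plogis(-t),
    ddphi = function(t) {
      e <- exp(-abs(t))
      e / (1 + e)^2
    }
  )
}

#' Solver settings
#'
#' @param tol relative objective tolerance of the outer loop.
#' @param max_iter maximum iterations (outer + coordinate sweeps).
#' @param kkt_tol tolerance on the sup-norm subgradient (KKT) residual;
#'   `converged = TRUE` certifies the residual is below it.
#' @export
solver_control <- function(tol = 1e-8, max_iter = 1e4, kkt_tol = 1e-6) {
  list(tol = tol, max_iter = as.integer(max_iter), kkt_tol = kkt_tol)
}

# column scales (uncentered root mean square; no intercept is used, so
# columns are scaled but not shifted)
column_scales <- function(x, standardize) {
  if (!standardize) return(rep(1, ncol(x)))
  s <- sqrt(colMeans(x^2))
  s[!is.finite(s) | s < 1e-12] <- 1
  s
}

#' Penalized weighted surrogate-loss minimizer
#'
#' Solves the convex program
#' \deqn{\hat\beta = \arg\min_\beta \; \frac1n \sum_i \left[
#'   \Omega^+_i \phi(x_i^\top\beta) + \Omega^-_i \phi(-x_i^\top\beta)\right]
#'   + \lambda \|\beta\|_1}
#' with the logistic surrogate, by iteratively reweighted coordinate
#' descent with warm starts.  The problem is a case-weighted binary
#' classification: each row contributes pseudo-label `+1` with weight
#' `Omega_plus` and `-1` with weight `Omega_minus`.  No intercept is fitted.
#'
#' With `standardize = TRUE` (default) columns are scaled to unit root mean
#' square internally, the l1 penalty applies to the coefficients of the
#' scaled columns (equivalently, penalty weights proportional to the column
#' scales in the original parametrization), and coefficients are mapped
#' back.  The reported `objective` and KKT residual refer to the problem
#' actually solved.
#'
#' @param x covariate matrix.
#' @param omega_plus,omega_minus nonnegative case weights.
#' @param lambda penalty level(s); a decreasing vector is fitted as a
#'   warm-started path.
#' @param standardize scale columns internally (see Details).
#' @param control a [solver_control()] list.
#' @return For a single `lambda`, an object of class `"surrogate_fit"` with
#'   `beta` (original scale), `objective`, `lambda`, `iterations`,
#'   `converged`, `kkt` and `penalty_scale`.  For a `lambda` vector, class
#'   `"surrogate_path"` with a `p x length(lambda)` matrix `beta`.
#' @export
penalized_surrogate <- function(x, omega_plus, omega_minus, lambda,
                                standardize = TRUE, control = solver_control()) {
  x <- as_matrix_x(x)
  n <- nrow(x)
  stopifnot(length(omega_plus) == n, length(omega_minus) == n)
  if (!all(is.finite(omega_plus)) || !all(is.finite(omega_minus)) ||
      any(omega_plus < 0) || any(omega_minus < 0))
    stop("'omega_plus'/'omega_minus' must be finite and nonnegative", call. = FALSE)
  if (any(lambda < 0) || length(lambda) < 1)
    stop("'lambda' must be nonnegative", call. = FALSE)
  if (all(omega_plus + omega_minus == 0)) {
    # degenerate problem: the loss is identically zero, 0 is a minimizer
    beta0 <- setNames(rep(0, ncol(x)), colnames(x))
    if (length(lambda) == 1L)
      return(structure(list(beta = beta0, objective = 0, lambda = lambda,
                            iterations = 0L, converged = TRUE, kkt = 0,
                            penalty_scale = column_scales(x, standardize),
                            degenerate = TRUE),
                       class = "surrogate_fit"))
    bm <- matrix(0, ncol(x), length(lambda), dimnames = list(colnames(x), NULL))
    return(structure(list(beta = bm, objective = rep(0, length(lambda)),
                          lambda = lambda, iterations = rep(0L, length(lambda)),
                          converged = rep(TRUE, length(lambda)),
                          kkt = rep(0, length(lambda)),
                          penalty_scale = column_scales(x, standardize),
                          degenerate = TRUE),
                     class = "surrogate_path"))
  }
  scl <- column_scales(x, standardize)
  xs <- sweep(x, 2, scl, "/")
  res <- cpp_surrogate_path(xs, omega_plus, omega_minus, as.numeric(lambda),
                            control$tol, control$max_iter, control$kkt_tol)
  beta <- sweep(res$beta, 1, scl, "/")
  rownames(beta) <- colnames(x)
  if (length(lambda) == 1L) {
    out <- structure(list(beta = drop(beta), objective = res$objective[1],
                          lambda = lambda, iterations = res$iterations[1],
                          converged = as.logical(res$converged[1]),
                          kkt = res$kkt[1], penalty_scale = scl),
                     class = "surrogate_fit")
    if (!out$converged)
      warning(sprintf("surrogate solver did not reach KKT tolerance (residual %.2e)",
                      out$kkt), call. = FALSE)
    out
  } else {
    structure(list(beta = beta, objective = res$objective, lambda = lambda,
                   iterations = res$iterations,
                   converged = as.logical(res$converged), kkt = res$kkt,
                   penalty_scale = scl),
              class = "surrogate_path")
  }
}

# unpenalized surrogate loss at beta (original scale)
surrogate_loss <- function(x, omega_plus, omega_minus, beta) {
  sg <- logistic_surrogate()
  t <- drop(x %*% beta)
  mean(omega_plus * sg$phi(t) + omega_minus * sg$phi(-t))
}

# default log-spaced grid centered at the (log p / n)^(1/2) rate anchor
lambda_grid <- function(n, p, grid_size, half_decades = 1.5) {
  anchor <- sqrt(log(max(p, 2)) / n)
  anchor * 10^seq(half_decades, -half_decades, length.out = grid_size)
}

#' Cross-validated penalty selection for the surrogate problem
#'
#' Chooses `lambda` minimizing the cross-validated (unpenalized) weighted
#' surrogate loss over a log-spaced grid centered at the theoretical rate
#' anchor `sqrt(log(p) / n)`.  Ties are broken towards the smallest
#' `lambda` (less shrinkage bias, which the one-step correction prefers).
#'
#' @inheritParams penalized_surrogate
#' @param grid penalty grid; `NULL` builds the default grid.
#' @param grid_size number of grid points when `grid` is `NULL`.
#' @param cv_folds number of cross-validation folds.
#' @param seed optional seed for the fold assignment.
#' @return list with the selected `lambda`, the `grid` and the vector of
#'   cross-validated losses `cv_loss`.
#' @export
select_lambda <- function(x, omega_plus, omega_minus, grid = NULL,
                          grid_size = 50, cv_folds = 5, seed = NULL,
                          standardize = TRUE, control = solver_control()) {
  x <- as_matrix_x(x)
  n <- nrow(x)
  if (is.null(grid)) grid <- lambda_grid(n, ncol(x), grid_size)
  if (length(grid) < 1 || any(grid < 0)) stop("degenerate penalty grid", call. = FALSE)
  grid <- sort(unique(as.numeric(grid)), decreasing = TRUE)
  if (length(grid) == 1L)
    return(list(lambda = grid, grid = grid, cv_loss = NA_real_))
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    loss <- matrix(0, cv_folds, length(grid))
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      path <- penalized_surrogate(x[tr, , drop = FALSE], omega_plus[tr],
                                  omega_minus[tr], grid,
                                  standardize = standardize, control = control)
      for (l in seq_along(grid))
        loss[f, l] <- sum(foldid == f) *
          surrogate_loss(x[!tr, , drop = FALSE], omega_plus[!tr],
                         omega_minus[!tr], path$beta[, l])
    }
    cvm <- colSums(loss) / n
    best <- which(cvm <= min(cvm) + 1e-12)
    lambda <- min(grid[best])
    list(lambda = lambda, grid = grid, cv_loss = cvm)
  })
}

#' Weighted-lasso de-correlation regression
#'
#' For inference on coordinate `j`, regresses `X_j` on the remaining
#' covariates under observation weights given by the second derivative of
#' the surrogate loss at the fitted rule:
#' \deqn{\hat w_j = \arg\min_w \; \frac1n \sum_i h_i
#'   (X_{ij} - X_{i,-j}^\top w)^2 + \tilde\lambda \|w\|_1.}
#' The residual `X_j - X_{-j}'w` orthogonalizes the score for coordinate
#' `j` against the estimation error of the remaining coefficients.
#'
#' @param x covariate matrix.
#' @param j coordinate under inference.
#' @param hweights nonnegative observation weights (`d2 l_phi` at the fitted
#'   coefficients); must not be all zero.
#' @param lambda_tilde penalty level(s).
#' @inheritParams penalized_surrogate
#' @return Class `"decor_fit"` (single penalty) with `w`, `objective`,
#'   `kkt`, `iterations`, `converged`; or class `"decor_path"` with a
#'   matrix `w` for a penalty vector.
#' @export
decorrelation_lasso <- function(x, j, hweights, lambda_tilde,
                                standardize = TRUE, control = solver_control()) {
  x <- as_matrix_x(x)
  p <- ncol(x)
  check_scalar(j, "j", lo = 1, hi = p, integer = TRUE)
  if (p < 2) stop("need at least two covariates", call. = FALSE)
  stopifnot(length(hweights) == nrow(x))
  if (!all(is.finite(hweights)) || any(hweights < 0))
    stop("'hweights' must be finite and nonnegative", call. = FALSE)
  if (sum(hweights) <= 0) stop("all observation weights are zero", call. = FALSE)
  if (any(lambda_tilde < 0)) stop("'lambda_tilde' must be nonnegative", call. = FALSE)
  xj <- x[, j]
  xm <- x[, -j, drop = FALSE]
  scl <- column_scales(xm, standardize)
  xs <- sweep(xm, 2, scl, "/")
  res <- cpp_wls_path(xs, xj, hweights, as.numeric(lambda_tilde),
                      control$tol, control$max_iter)
  w <- sweep(res$w, 1, scl, "/")
  rownames(w) <- colnames(xm)
  if (length(lambda_tilde) == 1L) {
    structure(list(w = drop(w), objective = res$objective[1],
                   lambda = lambda_tilde, iterations = res$iterations[1],
                   converged = as.logical(res$converged[1]), kkt = res$kkt[1]),
              class = "decor_fit")
  } else {
    structure(list(w = w, objective = res$objective, lambda = lambda_tilde,
                   iterations = res$iterations,
                   converged = as.logical(res$converged), kkt = res$kkt),
              class = "decor_path")
  }
}

#' Cross-validated penalty for the de-correlation regression
#'
#' Same grid convention and tie-breaking as [select_lambda()]; the
#' cross-validation criterion is the held-out weighted squared error.
#'
#' @inheritParams decorrelation_lasso
#' @inheritParams select_lambda
#' @export
select_lambda_tilde <- function(x, j, hweights, grid = NULL, grid_size = 50,
                                cv_folds = 5, seed = NULL, standardize = TRUE,
                                control = solver_control()) {
  x <- as_matrix_x(x)
  n <- nrow(x)
  if (is.null(grid)) grid <- lambda_grid(n, ncol(x), grid_size)
  grid <- sort(unique(as.numeric(grid)), decreasing = TRUE)
  if (length(grid) == 1L)
    return(list(lambda = grid, grid = grid, cv_loss = NA_real_))
  xj <- x[, j]
  xm <- x[, -j, drop = FALSE]
  with_seed(seed, {
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    loss <- matrix(0, cv_folds, length(grid))
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      fit <- decorrelation_lasso(x[tr, , drop = FALSE], j, hweights[tr], grid,
                                 standardize = standardize, control = control)
      resid <- xj[!tr] - xm[!tr, , drop = FALSE] %*% fit$w
      loss[f, ] <- colSums(hweights[!tr] * resid^2)
    }
    cvm <- colSums(loss) / n
    best <- which(cvm <= min(cvm) + 1e-12)
    list(lambda = min(grid[best]), grid = grid, cv_loss = cvm)
  })
}
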