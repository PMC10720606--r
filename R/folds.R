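#' Random cross-fitting partition
#'
#' Partitions `1:n` into `K` disjoint folds of near-equal size (every fold
#' has `floor(n/K)` or `floor(n/K) + 1` elements).  Nuisance models are
#' trained on each fold's complement and evaluated on the fold, so that the
#' rule estimator on a fold never uses nuisances fitted on its own rows.
#'
#' @param n number of observations; must satisfy `n >= 2 * K`.
#' @param K number of folds, at least 2.
#' @param seed optional integer seed (caller's RNG state is preserved).
#' @return An object of class `"crossfit_plan"`: list with `n`, `K` and
#'   `folds` (a list of index vectors).
#' @export
make_folds <- function(n, K = 2, seed = NULL) {
  check_scalar(n, "n", lo = 1, integer = TRUE)
  check_scalar(K, "K", lo = 2, integer = TRUE)
  if (n < 2 * K)
    stop(sprintf("need n >= 2K; got n = %d, K = %d", n, K), call. = FALSE)
  with_seed(seed, {
    sizes <- rep(n %/% K, K) + (seq_len(K) <= n %% K)
    assign <- sample(rep.int(seq_len(K), sizes))
    folds <- split(seq_len(n), assign)
    names(folds) <- NULL
    structure(list(n = as.integer(n), K = as.integer(K), folds = folds),
              class = "crossfit_plan")
  })
}

#' @export
#' @method print crossfit_plan
print.crossfit_plan <- function(x, ...) {
  cat(sprintf("cross-fitting plan: n = %d split into K = %d folds (sizes %s)\n",
              x$n, x$K, paste(lengths(x$folds), collapse = ", ")))
  invisible(x)
}
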