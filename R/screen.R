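#' Sample distance correlation
#'
#' Distance correlation (V-statistic form) between each column of `x` and a
#' response vector.  Constant columns get distance correlation 0.
#'
#' @param x numeric vector or matrix.
#' @param y numeric response vector.
#' @return A numeric vector of distance correlations, one per column of `x`.
#' @export
dist_cor <- function(x, y) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("dimension mismatch", call. = FALSE)
  drop(cpp_dcor(x, y))
}

#' Model-free variable screening by distance correlation
#'
#' Ranks covariates by their sample distance correlation with the response
#' and keeps the top `d` (sure-independence-screening style).  Ties are
#' broken in favour of the lower column index.
#'
#' @param x covariate matrix.
#' @param response numeric response (for propensity screening, the treatment
#'   indicator; for outcome screening, the outcome).
#' @param d screening budget; `floor(n / log(n))` is the customary default
#'   used by the nuisance fitters.
#' @return Sorted indices of the retained covariates
#'   (`min(d, ncol(x))` of them).
#' @export
screen_dcor <- function(x, response, d) {
  x <- as_matrix_x(x)
  check_scalar(d, "d", lo = 1, integer = TRUE)
  p <- ncol(x)
  if (p <= d) return(seq_len(p))
  dc <- dist_cor(x, response)
  keep <- order(-dc, seq_len(p))[seq_len(d)]
  sort(keep)
}
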