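`%||%` <- function(a, b) if (is.null(a)) b else a

# sign convention used throughout: sgn(0) = +1
sgn <- function(t) ifelse(t >= 0, 1, -1)

# Evaluate `code` under a temporary seed, restoring the caller's RNG state.
# With seed = NULL the current RNG stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

check_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("'%s' must lie in [%s, %s]", name, format(lo), format(hi)),
         call. = FALSE)
  invisible(x)
}

# map a treatment vector coded in {-1, 1} or {0, 1} onto {-1, 1}
as_treatment <- function(a) {
  if (!is.numeric(a)) stop("treatment must be numeric", call. = FALSE)
  if (anyNA(a)) stop("treatment contains missing values", call. = FALSE)
  u <- sort(unique(a))
  if (all(u %in% c(-1, 1))) return(as.numeric(a))
  if (all(u %in% c(0, 1))) return(ifelse(a == 0, -1, 1))
  stop("treatment must be coded in {-1, 1} or {0, 1}; found levels: ",
       paste(u, collapse = ", "), call. = FALSE)
}

as_matrix_x <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("'x' must be a numeric matrix", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  x
}
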