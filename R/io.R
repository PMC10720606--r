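#' Read an (X, A, Y) dataset from CSV
#'
#' Expects a comma-separated file with a header row, an outcome column, a
#' treatment column (coded `{-1, 1}` or `{0, 1}`; `0` maps to `-1`) and
#' numeric covariate columns.  Missing values are rejected with a location
#' report; imputation is deliberately out of scope.
#'
#' @param path file path.
#' @param outcome,treatment column names (defaults `"y"`, `"a"`).
#' @param covariates optional character vector of covariate columns;
#'   `NULL` uses every other column in file order.
#' @return An [itr_data()] object.
#' @export
read_itr_csv <- function(path, outcome = "y", treatment = "a", covariates = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c(outcome, treatment))
    if (!col %in% names(df)) stop("column not found: ", col, call. = FALSE)
  covariates <- covariates %||% setdiff(names(df), c(outcome, treatment))
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov))
    stop("covariate columns not found: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  bad <- covariates[!vapply(df[covariates], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric covariate columns: ", paste(bad, collapse = ", "),
         call. = FALSE)
  sub <- df[c(outcome, treatment, covariates)]
  na_cells <- which(is.na(as.matrix(sub)), arr.ind = TRUE)
  if (nrow(na_cells)) {
    loc <- apply(head(na_cells, 10), 1, function(rc)
      sprintf("row %d, column '%s'", rc[1], names(sub)[rc[2]]))
    stop(sprintf("missing values are not supported (%d found): %s%s",
                 nrow(na_cells), paste(loc, collapse = "; "),
                 if (nrow(na_cells) > 10) "; ..." else ""), call. = FALSE)
  }
  x <- as.matrix(df[covariates])
  itr_data(x, df[[treatment]], df[[outcome]])
}

#' Write an (X, A, Y) dataset to CSV
#'
#' Columns are written as `y, a, x1, ..., xp` at full double precision
#' (`%.17g`), so a write/read round trip reproduces the numeric values
#' exactly.
#'
#' @param data an [itr_data()] object.
#' @param path output file path.
#' @export
write_itr_csv <- function(data, path) {
  stopifnot(inherits(data, "itr_data"))
  cols <- c(list(data$y, data$a), lapply(seq_len(ncol(data$x)), function(j) data$x[, j]))
  txt <- lapply(cols, function(v) sprintf("%.17g", v))
  lines <- c(paste(c("y", "a", data$column_names), collapse = ","),
             do.call(paste, c(txt, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

# configuration defaults shared by the command-line interface
default_run_config <- function() {
  list(K = 2, seed = 1,
       propensity = "screened_kernel", outcome = "screened_kernel",
       trim = c(0.1, 0.9), alpha = 0.05, fdr = TRUE, coords = NULL,
       lambda = list(grid_size = 50, cv_folds = 5),
       solver = list(tol = 1e-8, max_iter = 1e4, kkt_tol = 1e-6),
       nuisance = list(cv_folds = 5, nlambda = 50, screen_d = NULL,
                       min_per_arm = 10, clip = 1e-6))
}

#' Read a run configuration
#'
#' Loads a YAML configuration and merges it over the package defaults;
#' entries not present in the file keep their default.  `path = NULL`
#' returns the defaults.
#'
#' @param path YAML file path or `NULL`.
#' @param overrides named list applied on top of the file values.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read configuration files",
           call. = FALSE)
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- modifyList(cfg, overrides)
  stopifnot(cfg$K >= 2, cfg$alpha > 0, cfg$alpha < 1,
            is.null(cfg$trim) || (length(cfg$trim) == 2 && cfg$trim[1] < cfg$trim[2]))
  cfg
}

#' Hash of a canonicalized configuration
#'
#' MD5 over the canonical (recursively name-sorted) JSON serialization, so
#' any change to any setting changes the hash while key order does not.
#'
#' @param cfg configuration list.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x) && !is.null(names(x))) lapply(x[order(names(x))], canon)
    else if (is.list(x)) lapply(x, canon) else x
  }
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(canon(cfg), auto_unbox = TRUE, digits = NA, null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

pearl_control_from_config <- function(cfg) {
  pearl_control(solver = do.call(solver_control, cfg$solver),
                lambda = cfg$lambda,
                nuisance = do.call(nuisance_control, cfg$nuisance))
}

# serializable record of a fitted rule (used by the CLI to pass fits
# between subcommands without refitting nuisances)
as_pearl_record <- function(fit) {
  list(version = as.character(utils::packageVersion("pearlitr")),
       n = fit$n, p = fit$p, K = fit$K, seed = fit$seed,
       propensity = fit$propensity, outcome = fit$outcome, trim = fit$trim,
       lambda = fit$lambda, coefficients = unname(fit$coefficients),
       column_names = names(fit$coefficients),
       folds = lapply(fit$fold, function(f)
         list(index = f$index, beta = unname(f$beta), lambda = f$lambda,
              pi1 = f$pi1, q1 = f$q1, qm1 = f$qm1,
              converged = f$converged)))
}

pearl_from_record <- function(record, data, control = pearl_control()) {
  stopifnot(inherits(data, "itr_data"))
  if (record$n != nrow(data$x) || record$p != ncol(data$x))
    stop("fit record does not match the dataset dimensions", call. = FALSE)
  folds <- lapply(record$folds, function(f) {
    idx <- as.integer(f$index)
    wts <- aipw_weights(data$y[idx], data$a[idx], f$pi1, f$q1, f$qm1)
    list(index = idx, pi1 = f$pi1, q1 = f$q1, qm1 = f$qm1, weights = wts,
         beta = as.numeric(f$beta), lambda = f$lambda,
         converged = isTRUE(f$converged), kkt = NA_real_,
         iterations = NA_integer_, objective = NA_real_)
  })
  beta <- as.numeric(record$coefficients)
  names(beta) <- record$column_names
  structure(list(coefficients = beta, fold = folds,
                 plan = structure(list(n = record$n, K = record$K,
                                       folds = lapply(folds, `[[`, "index")),
                                  class = "crossfit_plan"),
                 K = record$K, n = record$n, p = record$p, trim = record$trim,
                 propensity = record$propensity, outcome = record$outcome,
                 lambda = as.numeric(record$lambda), control = control,
                 seed = record$seed, call = quote(pearl_from_record()),
                 x = data$x, a = data$a, y = data$y),
            class = "pearl")
}

#' Write a machine- and human-readable run report
#'
#' @param fit a [pearl()] fit.
#' @param infer optional [pearl_infer()] table.
#' @param value optional [value_ci()] result.
#' @param path output stem; `<path>.json` and `<path>.txt` are written.
#' @param config optional configuration list recorded (with its hash) in
#'   the report.
#' @return Invisibly, the paths written.
#' @export
run_report <- function(fit, infer = NULL, value = NULL, path, config = NULL) {
  payload <- list(package = "pearlitr",
                  version = as.character(utils::packageVersion("pearlitr")),
                  config = config,
                  config_hash = if (!is.null(config)) config_hash(config),
                  fit = as_pearl_record(fit))
  if (!is.null(infer)) payload$inference <- as.data.frame(infer)
  if (!is.null(value))
    payload$value <- list(v_hat = value$v_hat, se = value$se,
                          sigma_v = value$sigma_v, ci = unname(value$ci),
                          n1 = value$n1, n2 = value$n2, level = value$level)
  json_path <- paste0(path, ".json")
  txt_path <- paste0(path, ".txt")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  txt <- c(capture.output(print(fit)),
           if (!is.null(infer)) c("", capture.output(print(infer))),
           if (!is.null(value)) c("", capture.output(print(value))))
  writeLines(txt, txt_path)
  invisible(c(json = json_path, txt = txt_path))
}
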