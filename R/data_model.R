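#' Assemble a mixture dataset for kernel machine regression
#'
#' Builds the validated container used by [kmr()]: a continuous outcome, an
#' n x M matrix of continuous exposures (z-scored by default, optionally
#' log-transformed first), a covariate design matrix with an intercept, and a
#' categorical modifier recoded to consecutive integer levels `1..P` in order
#' of first appearance. Rows with missing values in any used column are
#' dropped with a message.
#'
#' @param data A data.frame containing all columns named below.
#' @param outcome Name of the continuous outcome column.
#' @param exposures Character vector of exposure column names (length M >= 1).
#' @param covariates Character vector of covariate column names (may be
#'   empty). Factors and characters are expanded to indicators via
#'   [stats::model.matrix()].
#' @param modifier Optional name of a categorical modifier column. `NULL`
#'   means no modifier (a single group).
#' @param log_exposures If `TRUE`, exposures are log-transformed before
#'   z-scoring; all exposure values must then be strictly positive. Intended
#'   for positively skewed concentrations such as metals.
#' @param standardize If `TRUE` (default) exposures are z-scored; the
#'   centering/scaling record is kept so quantile contrasts can be expressed
#'   on the original scale.
#'
#' @return An object of class `mixture_data`: a list with elements `y`, `Z`
#'   (standardized exposures), `Z_orig` (original scale), `X` (covariate
#'   design matrix including intercept, excluding modifier indicators), `w`
#'   (integer modifier labels in `1..P`), `levels` (original modifier labels
#'   in internal order), `std` (standardization record), `names` (column-name
#'   bookkeeping), and `n`, `M`, `P`.
#' @export
#' @examples
#' df <- data.frame(y = rnorm(20), a = rexp(20), b = rexp(20),
#'                  sex = rep(c("f", "m"), 10), age = rnorm(20))
#' d <- mixture_data(df, outcome = "y", exposures = c("a", "b"),
#'                   covariates = "age", modifier = "sex")
#' d$P
mixture_data <- function(data, outcome, exposures, covariates = character(),
                         modifier = NULL, log_exposures = FALSE,
                         standardize = TRUE) {
  stopifnot(is.data.frame(data), length(outcome) == 1L, length(exposures) >= 1L)
  used <- c(outcome, exposures, covariates, modifier)
  missing_cols <- setdiff(used, names(data))
  if (length(missing_cols)) {
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  }
  levels_pre <- if (!is.null(modifier)) unique(as.character(data[[modifier]]))
  keep <- stats::complete.cases(data[, used, drop = FALSE])
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("mixture_data: dropped ", n_dropped, " row(s) with missing values")
    data <- data[keep, , drop = FALSE]
  }
  n <- nrow(data)
  if (n < 2L) stop("fewer than 2 complete rows")

  y <- data[[outcome]]
  if (!is.numeric(y)) stop("outcome column '", outcome, "' is not numeric")
  Z_orig <- as.matrix(data[, exposures, drop = FALSE])
  if (!is.numeric(Z_orig)) stop("non-numeric exposure column among: ",
                                paste(exposures, collapse = ", "))
  storage.mode(Z_orig) <- "double"
  v <- apply(Z_orig, 2L, stats::var)
  if (any(v <= 0)) {
    stop("exposure column(s) with zero variance: ",
         paste(exposures[v <= 0], collapse = ", "))
  }

  # modifier: internal codes 1..P by first appearance, original labels kept
  if (is.null(modifier)) {
    w <- rep.int(1L, n)
    levels_w <- "all"
  } else {
    raw <- as.character(data[[modifier]])
    levels_w <- levels_pre[!is.na(levels_pre)]
    w <- match(raw, levels_w)
    counts <- tabulate(w, nbins = length(levels_w))
    if (any(counts == 0L))
      stop("modifier level with zero rows after dropping: ",
           paste(levels_w[counts == 0L], collapse = ", "))
  }

  if (length(covariates)) {
    X <- stats::model.matrix(~ ., data = data[, covariates, drop = FALSE])
  } else {
    X <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }

  sd_res <- standardize_exposures(Z_orig, log_transform = log_exposures,
                                  center_scale = standardize)
  out <- list(
    y = as.numeric(y), Z = sd_res$Z, Z_orig = Z_orig, X = X,
    w = as.integer(w), levels = levels_w, std = sd_res$record,
    names = list(outcome = outcome, exposures = exposures,
                 covariates = covariates, modifier = modifier),
    n = n, M = ncol(Z_orig), P = length(levels_w)
  )
  class(out) <- "mixture_data"
  validate_mixture_data(out)
  out
}

validate_mixture_data <- function(d) {
  stopifnot(inherits(d, "mixture_data"))
  n <- d$n
  if (length(d$y) != n || nrow(d$Z) != n || nrow(d$X) != n || length(d$w) != n)
    stop("inconsistent dimensions in mixture_data")
  if (anyNA(d$y) || anyNA(d$Z) || anyNA(d$X) || anyNA(d$w))
    stop("missing values in mixture_data")
  if (!all(seq_len(d$P) %in% d$w)) stop("empty modifier level")
  if (any(apply(d$Z, 2L, stats::var) <= 0)) stop("zero-variance exposure column")
  invisible(d)
}

#' Encode a categorical modifier as group-membership indicators
#'
#' Converts modifier labels into an n x (P-1) indicator matrix with one
#' reference level omitted, as used by the modifier-in-kernel model. Column
#' order follows sorted non-reference levels.
#'
#' @param w Vector of modifier labels (integer, character or factor).
#' @param reference The reference level (omitted from the indicators).
#'   Defaults to the first sorted level.
#' @return A list of class `modifier_encoding` with elements `D` (the n x
#'   (P-1) 0/1 matrix), `reference`, and `levels` (column level of each
#'   indicator column).
#' @export
#' @examples
#' encode_modifier(c(1, 2, 3, 2), reference = 1)$D
encode_modifier <- function(w, reference = NULL) {
  lev <- sort(unique(w))
  P <- length(lev)
  if (P < 2L) stop("modifier has a single level; use the standard variant")
  if (is.null(reference)) reference <- lev[1L]
  if (!reference %in% lev) stop("reference level not observed in w")
  cols <- lev[lev != reference]
  D <- vapply(cols, function(l) as.numeric(w == l), numeric(length(w)))
  D <- matrix(D, nrow = length(w), ncol = P - 1L,
              dimnames = list(NULL, paste0("mod", cols)))
  structure(list(D = D, reference = reference, levels = cols),
            class = "modifier_encoding")
}

#' Recover modifier labels from an indicator encoding
#'
#' @param enc A `modifier_encoding` from [encode_modifier()].
#' @return The label vector that produced the encoding.
#' @export
decode_modifier <- function(enc) {
  stopifnot(inherits(enc, "modifier_encoding"))
  idx <- as.integer(enc$D %*% seq_along(enc$levels))
  out <- c(enc$reference, enc$levels)[idx + 1L]
  out
}

#' Center and scale exposure columns
#'
#' z-scores each exposure column (optionally after a log transform) and
#' returns the record needed to map quantile contrasts back to the original
#' scale.
#'
#' @param Z Numeric exposure matrix.
#' @param log_transform If `TRUE`, take logs first; requires all entries > 0.
#' @param center_scale If `FALSE`, only the optional log transform is applied.
#' @return A list with `Z` (transformed matrix) and `record` (list with
#'   `center`, `scale`, `log`).
#' @export
standardize_exposures <- function(Z, log_transform = FALSE,
                                  center_scale = TRUE) {
  Z <- as.matrix(Z)
  if (log_transform) {
    if (any(Z <= 0)) stop("log transform requires strictly positive exposures")
    Z <- log(Z)
  }
  if (center_scale) {
    ctr <- colMeans(Z)
    scl <- apply(Z, 2L, stats::sd)
    if (any(scl <= 0)) stop("zero-variance exposure column")
    Z <- sweep(sweep(Z, 2L, ctr, "-"), 2L, scl, "/")
  } else {
    ctr <- rep(0, ncol(Z))
    scl <- rep(1, ncol(Z))
  }
  list(Z = Z, record = list(center = ctr, scale = scl, log = log_transform))
}

#' Map exposure values between original and standardized scales
#'
#' @param Z Matrix or vector of exposure values (columns in exposure order).
#' @param record A standardization record from [standardize_exposures()].
#' @return The transformed values.
#' @export
apply_standardization <- function(Z, record) {
  Z <- if (is.matrix(Z)) Z else matrix(Z, nrow = 1L)
  if (record$log) {
    if (any(Z <= 0)) stop("log transform requires strictly positive exposures")
    Z <- log(Z)
  }
  sweep(sweep(Z, 2L, record$center, "-"), 2L, record$scale, "/")
}

#' @rdname apply_standardization
#' @export
invert_standardization <- function(Z, record) {
  Z <- if (is.matrix(Z)) Z else matrix(Z, nrow = 1L)
  Z <- sweep(sweep(Z, 2L, record$scale, "*"), 2L, record$center, "+")
  if (record$log) Z <- exp(Z)
  Z
}

#' Read a mixture dataset from a CSV file
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Either a list mapping roles to column names (elements
#'   `outcome`, `exposures`, and optionally `covariates`, `modifier`) or a
#'   path to a JSON/YAML file with those fields.
#' @param ... Passed to [mixture_data()] (e.g. `log_exposures`).
#' @return A `mixture_data` object.
#' @export
read_mixture_data <- function(path, schema, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.character(schema) && length(schema) == 1L) schema <- read_config(schema)
  if (is.null(schema$outcome) || is.null(schema$exposures))
    stop("schema must name an outcome and at least one exposure column")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mixture_data(df, outcome = schema$outcome, exposures = schema$exposures,
               covariates = schema$covariates %||% character(),
               modifier = schema$modifier, ...)
}

#' Write a mixture dataset back to CSV (original exposure scale)
#'
#' @param dataset A `mixture_data` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mixture_data <- function(dataset, path) {
  stopifnot(inherits(dataset, "mixture_data"))
  df <- data.frame(dataset$y, dataset$Z_orig, check.names = FALSE)
  names(df) <- c(dataset$names$outcome, dataset$names$exposures)
  cov_cols <- setdiff(colnames(dataset$X), "(Intercept)")
  if (length(cov_cols)) df[cov_cols] <- dataset$X[, cov_cols, drop = FALSE]
  if (!is.null(dataset$names$modifier)) {
    df[[dataset$names$modifier]] <- dataset$levels[dataset$w]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Summarize a mixture dataset
#'
#' Group counts and per-exposure quantiles (original scale), suitable for
#' logging or JSON export.
#'
#' @param object A `mixture_data`.
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @return A list with `n`, `groups`, and `exposure_quantiles`.
#' @export
summary.mixture_data <- function(object,
                                 probs = c(0.05, 0.25, 0.5, 0.75, 0.95), ...) {
  counts <- as.integer(tabulate(object$w, nbins = object$P))
  names(counts) <- object$levels
  qs <- apply(object$Z_orig, 2L, stats::quantile, probs = probs, type = 7)
  out <- list(n = object$n, M = object$M, P = object$P, groups = counts,
              exposure_quantiles = qs)
  class(out) <- "summary.mixture_data"
  out
}

#' @export
print.summary.mixture_data <- function(x, ...) {
  cat("Mixture dataset: n =", x$n, ", M =", x$M, "exposures, P =", x$P,
      "modifier level(s)\n")
  cat("Group counts:\n")
  print(x$groups)
  cat("Exposure quantiles (original scale):\n")
  print(x$exposure_quantiles)
  invisible(x)
}

#' @export
print.mixture_data <- function(x, ...) {
  cat("<mixture_data> n =", x$n, ", M =", x$M, ", P =", x$P, "\n")
  cat("  outcome:  ", x$names$outcome, "\n")
  cat("  exposures:", paste(x$names$exposures, collapse = ", "), "\n")
  if (!is.null(x$names$modifier))
    cat("  modifier: ", x$names$modifier, "(levels:",
        paste(x$levels, collapse = ", "), ")\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
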