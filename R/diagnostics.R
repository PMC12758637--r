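#' Effective sample size of an MCMC chain
#'
#' Autocorrelation-adjusted effective sample size
#' `N / (1 + 2 * sum(acf))`, with the autocorrelation sum truncated by
#' Geyer's initial-positive-sequence rule (summation stops when a
#' consecutive lag-pair sum turns negative) and the result capped at N.
#'
#' @param chain Numeric vector of draws (length >= 10, nonconstant).
#' @return The effective sample size.
#' @export
effective_sample_size <- function(chain) {
  n <- length(chain)
  if (n < 10L) stop("chain too short for ESS estimation")
  if (stats::var(chain) == 0) stop("constant chain: degenerate parameter")
  max_lag <- min(n - 2L, floor(10 * log10(n)) * 5L)
  ac <- stats::acf(chain, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[-1L]
  # initial positive sequence: sum pairs (rho_1+rho_2), (rho_3+rho_4), ...
  s <- 0
  k <- 1L
  while (k + 1L <= length(ac)) {
    pair <- ac[k] + ac[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  if (k <= length(ac) && k %% 2L == 1L && k + 1L > length(ac) && ac[k] > 0)
    s <- s + ac[k]
  min(n, n / (1 + 2 * s))
}

#' Geweke convergence z-score
#'
#' Compares the mean of an early chain segment with the mean of a late
#' segment: `z = (mean_first - mean_last) / sqrt(s1/n1 + s2/n2)`, where the
#' variance of each segment mean uses a spectral-density-at-zero estimate
#' from non-overlapping batch means (about sqrt(segment length) batches).
#'
#' @param chain Numeric vector of draws.
#' @param frac_first Fraction of the chain in the early segment.
#' @param frac_last Fraction of the chain in the late segment.
#' @return The z statistic.
#' @export
geweke_z <- function(chain, frac_first = 0.1, frac_last = 0.5) {
  n <- length(chain)
  if (frac_first <= 0 || frac_last <= 0 || frac_first + frac_last > 1)
    stop("segment fractions must be positive and sum to at most 1")
  n1 <- floor(frac_first * n)
  n2 <- floor(frac_last * n)
  if (n1 < 10L || n2 < 10L) stop("segments too short (need >= 10 draws each)")
  a <- chain[seq_len(n1)]
  b <- chain[seq.int(n - n2 + 1L, n)]
  sv <- function(x) {
    nb <- max(2L, floor(sqrt(length(x))))
    bs <- length(x) %/% nb
    bm <- vapply(seq_len(nb), function(i) {
      mean(x[seq.int((i - 1L) * bs + 1L, i * bs)])
    }, numeric(1L))
    v <- stats::var(bm) * bs  # spectral density at zero estimate
    if (!is.finite(v) || v == 0) stop("degenerate segment variance")
    v
  }
  (mean(a) - mean(b)) / sqrt(sv(a) / n1 + sv(b) / n2)
}

#' Convergence diagnostics for a fitted model
#'
#' Effective sample size, Geweke z and flags for every scalar chain of a
#' fit, plus the Metropolis acceptance rates. Degenerate (constant) chains
#' are reported as flagged rows, not errors.
#'
#' @param fit A `kmr` or `kmr_stratified` fit.
#' @param ess_threshold Flag parameters with ESS below this value.
#' @param z_threshold Flag parameters with |Geweke z| above this value.
#' @return An object of class `kmr_diagnostics`: a data.frame with columns
#'   `parameter`, `ess`, `geweke_z`, `flag`, with acceptance rates attached
#'   as an attribute.
#' @export
diagnostics_report <- function(fit, ess_threshold = 100, z_threshold = 2) {
  if (inherits(fit, "kmr_stratified")) {
    out <- do.call(rbind, lapply(seq_along(fit$fits), function(g) {
      r <- diagnostics_report(fit$fits[[g]], ess_threshold, z_threshold)
      r$parameter <- paste0("g", g, ".", r$parameter)
      r
    }))
    class(out) <- c("kmr_diagnostics", "data.frame")
    return(out)
  }
  stopifnot(inherits(fit, "kmr"))
  ch <- chain_matrix(fit)
  rows <- lapply(colnames(ch), function(p) {
    v <- ch[, p]
    ess <- tryCatch(effective_sample_size(v), error = function(e) NA_real_)
    z <- tryCatch(geweke_z(v), error = function(e) NA_real_)
    flag <- is.na(ess) || is.na(z) || ess < ess_threshold || abs(z) > z_threshold
    data.frame(parameter = p, ess = ess, geweke_z = z, flag = flag)
  })
  out <- do.call(rbind, rows)
  attr(out, "acceptance") <- fit$acceptance
  class(out) <- c("kmr_diagnostics", "data.frame")
  out
}

#' @export
print.kmr_diagnostics <- function(x, ...) {
  cat("MCMC diagnostics (", sum(x$flag), "of", nrow(x),
      "parameters flagged)\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export chain traces in long format
#'
#' @param fit A `kmr` fit.
#' @param path Optional CSV path; if given the table is written there.
#' @return A long-format data.frame (`iteration`, `parameter`, `value`).
#' @export
trace_export <- function(fit, path = NULL) {
  ch <- chain_matrix(fit)
  out <- data.frame(
    iteration = rep(seq_len(nrow(ch)), times = ncol(ch)),
    parameter = rep(colnames(ch), each = nrow(ch)),
    value = as.vector(ch)
  )
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
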