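#' @export
print.kmr <- function(x, ...) {
  cat("Bayesian kernel machine regression fit\n")
  cat("  variant:  ", x$variant, "\n")
  cat("  n =", x$dataset$n, ", M =", x$dataset$M, "exposures, P =",
      x$dataset$P, "group(s)\n")
  cat("  draws:    ", x$n_draws, "retained (", x$control$iter, "iterations,",
      x$control$burnin, "burn-in, thin", x$control$thin, ")\n")
  cat("  acceptance: lambda",
      paste(sprintf("%.2f", x$acceptance$lambda), collapse = " "),
      "| r", paste(sprintf("%.2f", x$acceptance$r), collapse = " "), "\n")
  invisible(x)
}

#' Posterior summary of a kernel machine regression fit
#'
#' Posterior means, 95% credible intervals and convergence diagnostics for
#' every scalar parameter (covariate coefficients, residual variance, the
#' variance ratio(s) lambda and inverse bandwidths r).
#'
#' @param object A `kmr` fit.
#' @param ... Unused.
#' @return A data.frame with one row per parameter.
#' @export
summary.kmr <- function(object, ...) {
  ch <- chain_matrix(object)
  out <- data.frame(
    parameter = colnames(ch),
    mean = colMeans(ch),
    lower = apply(ch, 2L, stats::quantile, 0.025, type = 7),
    upper = apply(ch, 2L, stats::quantile, 0.975, type = 7),
    ess = apply(ch, 2L, function(v) {
      tryCatch(effective_sample_size(v), error = function(e) NA_real_)
    }),
    row.names = NULL
  )
  class(out) <- c("summary.kmr", "data.frame")
  out
}

#' @export
print.summary.kmr <- function(x, digits = 3, ...) {
  cat("Posterior summary (mean, 95% CrI, ESS):\n")
  print.data.frame(format(x, digits = digits), row.names = FALSE)
  invisible(x)
}

# all scalar chains, indicator-expanded, named
chain_matrix <- function(fit) {
  b <- fit$draws$beta
  colnames(b) <- paste0("beta.", colnames(fit$X) %||% seq_len(ncol(b)))
  lam <- fit$draws$lambda
  colnames(lam) <- if (ncol(lam) == 1L) "lambda" else
    paste0("lambda.", seq_len(ncol(lam)))
  r <- fit$draws$r
  colnames(r) <- paste0("r.", seq_len(ncol(r)))
  cbind(b, sigma2 = fit$draws$sigma2, lam, r)
}

#' @export
coef.kmr <- function(object, ...) {
  colMeans(object$draws$beta)
}

#' Posterior surface prediction at new exposure points
#'
#' Posterior mean (and credible interval) of the exposure-response surface h
#' at new exposure values, via Gaussian-process conditioning per retained
#' draw.
#'
#' @param object A `kmr` fit.
#' @param newdata Matrix (q x M) of exposure values on the original scale;
#'   defaults to the training exposures.
#' @param group Group codes/labels of the query rows (recycled).
#' @param sample If `TRUE` sample one surface realization per draw (draws
#'   attached as attribute); otherwise use conditional means.
#' @param ... Unused.
#' @return A data.frame with columns `mean`, `lower`, `upper`.
#' @export
predict.kmr <- function(object, newdata = NULL, group = 1L, sample = FALSE,
                        ...) {
  d <- object$dataset
  Zq_orig <- if (is.null(newdata)) d$Z_orig else as.matrix(newdata)
  if (ncol(Zq_orig) != d$M) stop("newdata must have ", d$M, " columns")
  wq <- vapply(rep(group, length.out = nrow(Zq_orig)),
               function(g) resolve_group(d, g), integer(1L))
  Zq <- apply_standardization(Zq_orig, d$std)
  h <- posterior_h_samples(object, Zq, wq, sample = sample,
                           seed_key = nrow(Zq))
  out <- data.frame(mean = colMeans(h),
                    lower = apply(h, 2L, stats::quantile, 0.025, type = 7),
                    upper = apply(h, 2L, stats::quantile, 0.975, type = 7))
  if (sample) attr(out, "draws") <- h
  out
}

#' @export
fitted.kmr <- function(object, ...) {
  hbar <- predict.kmr(object, group = object$dataset$w)$mean
  drop(object$X %*% coef(object)) + hbar
}

#' @export
residuals.kmr <- function(object, ...) {
  object$dataset$y - fitted(object)
}

#' Trace plots for a kernel machine regression fit
#'
#' @param x A `kmr` fit.
#' @param parameters Optional character vector of chain names (see
#'   [summary.kmr()]); defaults to `sigma2`, the lambda components and the
#'   first inverse bandwidth.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.kmr <- function(x, parameters = NULL, ...) {
  ch <- chain_matrix(x)
  if (is.null(parameters)) {
    parameters <- c("sigma2", grep("^lambda", colnames(ch), value = TRUE),
                    "r.1")
  }
  parameters <- intersect(parameters, colnames(ch))
  old <- graphics::par(mfrow = c(length(parameters), 1L),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in parameters) {
    graphics::plot(ch[, p], type = "l", ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Posterior predictive simulation
#'
#' Draws new outcome vectors at the training design: for each requested
#' simulation a retained posterior draw is selected, a surface realization is
#' sampled at the training points, and Gaussian residual noise is added.
#'
#' @param object A `kmr` fit.
#' @param nsim Number of simulated outcome vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A data.frame with `nsim` columns of length n.
#' @export
simulate.kmr <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$dataset
  idx <- sample.int(object$n_draws, nsim, replace = TRUE)
  h <- posterior_h_samples(object, d$Z, d$w, sample = TRUE,
                           seed_key = 7919L + nsim)
  out <- vapply(seq_len(nsim), function(j) {
    i <- idx[j]
    drop(object$X %*% object$draws$beta[i, ]) + h[i, ] +
      stats::rnorm(d$n, 0, sqrt(object$draws$sigma2[i]))
  }, numeric(d$n))
  as.data.frame(out)
}

#' @export
print.kmr_stratified <- function(x, ...) {
  cat("Stratified kernel machine regression:", length(x$fits), "fits\n")
  for (g in seq_along(x$fits)) {
    cat(sprintf("  group %s (n = %d)\n", x$levels[g], x$fits[[g]]$dataset$n))
  }
  invisible(x)
}

#' @export
summary.kmr_stratified <- function(object, ...) {
  out <- lapply(object$fits, summary)
  names(out) <- object$levels
  out
}
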