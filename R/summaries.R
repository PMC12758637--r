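#' Empirical exposure quantiles
#'
#' Per-exposure empirical quantiles (type-7 interpolation) on the original
#' exposure scale, either pooled over all rows or within one modifier group.
#'
#' @param dataset A `mixture_data`.
#' @param q Quantile in (0, 1).
#' @param scope `"pooled"` (default) uses all rows; `"by_group"` uses only
#'   rows of `group`.
#' @param group Group (internal code or label) when `scope = "by_group"`.
#' @return Named length-M vector of quantile values.
#' @export
quantile_points <- function(dataset, q, scope = c("pooled", "by_group"),
                            group = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(dataset, "mixture_data"), q > 0, q < 1)
  Z <- dataset$Z_orig
  if (scope == "by_group") {
    g <- resolve_group(dataset, group)
    Z <- Z[dataset$w == g, , drop = FALSE]
  }
  apply(Z, 2L, stats::quantile, probs = q, type = 7, names = FALSE)
}

resolve_group <- function(dataset, group) {
  if (is.null(group)) return(1L)
  if (is.character(group)) {
    g <- match(group, dataset$levels)
    if (is.na(g)) stop("unknown group label '", group, "'")
    return(g)
  }
  g <- as.integer(group)
  if (g < 1L || g > dataset$P) stop("group code out of range 1..", dataset$P)
  g
}

# Deterministic RNG scope: effect summaries recomputed from the same fit are
# identical, and the caller's random-number stream is left untouched.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# Posterior samples (or conditional means) of the surface h at query points.
# For each retained draw, h(query) | y, beta, sigma2, lambda, r is Gaussian
# with mean K_q V^-1 (y - X beta) and covariance K_qq - K_q V^-1 K_q', where
# V = tau K + sigma2 I; one realization is sampled per draw. Group-separable
# query points condition only on their own group's block; each block
# consumes its own RNG stream segment in group order.
posterior_h_samples <- function(fit, Zq_std, wq = NULL, sample = TRUE,
                                seed_key = 0L) {
  stopifnot(inherits(fit, "kmr"))
  d <- fit$dataset
  Zq_std <- as.matrix(Zq_std)
  q <- nrow(Zq_std)
  if (is.null(wq)) wq <- rep.int(1L, q)
  bl <- kmr_blocks(d, fit$variant, fit$reference)

  if (fit$variant == "modifier_in_kernel") {
    enc <- encode_modifier(d$w, reference = fit$reference)
    Q <- cbind(Zq_std, indicator_rows(wq, enc))
    q_in_block <- list(seq_len(q))
  } else if (fit$variant == "group_separable") {
    Q <- Zq_std
    q_in_block <- lapply(seq_len(d$P), function(g) which(wq == g))
  } else {
    Q <- Zq_std
    q_in_block <- list(seq_len(q))
  }

  nd <- fit$n_draws
  y <- d$y
  X <- fit$X
  out <- matrix(NA_real_, nd, q)
  n_lam <- ncol(fit$draws$lambda)
  seed <- derive_seed((fit$control$seed %||% 0) + seed_key, 104729 + q)
  with_local_seed(seed, {
    for (i in seq_len(nd)) {
      r_i <- fit$draws$r[i, ]
      sigma2_i <- fit$draws$sigma2[i]
      lam_i <- rep(fit$draws$lambda[i, ], length.out = bl$n_lambda)
      resid <- y - drop(X %*% fit$draws$beta[i, ])
      for (g in seq_along(bl$blocks)) {
        qs <- q_in_block[[min(g, length(q_in_block))]]
        if (g > length(q_in_block) || !length(qs)) next
        b <- bl$blocks[[g]]
        K <- kernel_from_sqdist(b$S, r_i)
        lam <- lam_i[g]
        V1 <- lam * K
        diag(V1) <- diag(V1) + 1 + .kmr_jitter * lam
        R <- chol(V1)
        A <- gaussian_kernel(Q[qs, , drop = FALSE],
                             bl$Zk[b$idx, , drop = FALSE], 1 / r_i)
        C_qq <- gaussian_kernel(Q[qs, , drop = FALSE],
                                Q[qs, , drop = FALSE], 1 / r_i)
        W <- backsolve(R, t(A), transpose = TRUE)
        u <- backsolve(R, resid[b$idx], transpose = TRUE)
        mu <- lam * drop(crossprod(W, u))
        if (sample) {
          Cc <- sigma2_i * lam * (C_qq - lam * crossprod(W))
          Cc <- (Cc + t(Cc)) / 2
          jit <- 1e-10 + 1e-8 * max(diag(Cc), 0)
          diag(Cc) <- diag(Cc) + jit
          Rc <- tryCatch(chol(Cc), error = function(e) NULL)
          if (is.null(Rc)) {
            eg <- eigen(Cc, symmetric = TRUE)
            ev <- pmax(eg$values, 0)
            draw <- mu + drop(eg$vectors %*% (sqrt(ev) * stats::rnorm(length(qs))))
          } else {
            draw <- mu + drop(crossprod(Rc, stats::rnorm(length(qs))))
          }
          out[i, qs] <- draw
        } else {
          out[i, qs] <- mu
        }
      }
    }
  })
  out
}

# Canonical query handling: dedupe (point, group) rows so that identical
# endpoints give exactly-zero contrasts and reversed quantiles give exactly
# negated draws.
h_contrast_core <- function(fit, pts_orig, wq, ia, ib, sample = TRUE) {
  d <- fit$dataset
  if (fit$variant == "standard") wq <- rep.int(1L, length(wq))
  key <- apply(cbind(signif(pts_orig, 12), wq), 1L, paste, collapse = "|")
  ord <- order(key)
  uniq <- !duplicated(key[ord])
  canon <- ord[uniq]
  map <- match(key, key[canon])
  Zq <- apply_standardization(pts_orig[canon, , drop = FALSE], d$std)
  h <- posterior_h_samples(fit, Zq, wq[canon], sample = sample,
                           seed_key = sum(wq) + length(canon))
  h[, map[ia], drop = FALSE] - h[, map[ib], drop = FALSE]
}

#' Posterior contrast draws between two exposure points
#'
#' For each retained MCMC draw, samples the surface difference
#' `h(point_a) - h(point_b)` from the joint conditional normal of the two
#' surface values given the data and that draw's parameters.
#'
#' @param fit A `kmr` fit.
#' @param point_a,point_b Length-M exposure vectors on the original scale.
#' @param group_a,group_b Group (code or label) giving each point its surface;
#'   ignored by the standard variant.
#' @return Numeric vector of contrast draws (one per retained draw).
#' @export
sample_h_contrast <- function(fit, point_a, point_b, group_a = 1L,
                              group_b = group_a) {
  d <- fit$dataset
  ga <- resolve_group(d, group_a); gb <- resolve_group(d, group_b)
  pts <- rbind(as.numeric(point_a), as.numeric(point_b))
  drop(h_contrast_core(fit, pts, c(ga, gb), 1L, 2L))
}

new_effect <- function(draws, query, group_label) {
  draws <- as.numeric(draws)
  structure(list(
    mean = mean(draws),
    lower = stats::quantile(draws, 0.025, names = FALSE, type = 7),
    upper = stats::quantile(draws, 0.975, names = FALSE, type = 7),
    draws = draws, query = query, group = group_label
  ), class = "kmr_effect")
}

#' @export
print.kmr_effect <- function(x, digits = 4, ...) {
  cat(sprintf("%s effect [%s]: %.*f (95%% CrI %.*f, %.*f)\n",
              x$query$kind, paste(x$group, collapse = " - "),
              digits, x$mean, digits, x$lower, digits, x$upper))
  invisible(x)
}

#' Total mixture effect
#'
#' Difference in expected outcome when every exposure is fixed at quantile
#' `q2` versus all fixed at quantile `q1`, for one modifier group; posterior
#' mean and 95% credible interval from draw-wise surface contrasts.
#'
#' @param fit A `kmr` or `kmr_stratified` fit.
#' @param q1 Baseline quantile (the analysis convention compares against the
#'   median, `q1 = 0.5`).
#' @param q2 Comparison quantile.
#' @param group Modifier group (code or label).
#' @param scope Quantile scope, `"pooled"` (default) or `"by_group"`.
#' @return A `kmr_effect`.
#' @export
total_mixture_effect <- function(fit, q1 = 0.5, q2 = 0.75, group = 1L,
                                 scope = "pooled") {
  UseMethod("total_mixture_effect")
}

#' @export
total_mixture_effect.kmr <- function(fit, q1 = 0.5, q2 = 0.75, group = 1L,
                                     scope = "pooled", .dataset = NULL) {
  d <- .dataset %||% fit$dataset
  g <- resolve_group(d, group)
  gq <- if (fit$dataset$P == 1L) 1L else resolve_group(fit$dataset, group)
  pa <- quantile_points(d, q2, scope = scope, group = group)
  pb <- quantile_points(d, q1, scope = scope, group = group)
  draws <- h_contrast_core(fit, rbind(pa, pb), c(gq, gq), 1L, 2L)
  new_effect(draws,
             list(kind = "total_mixture", q1 = q1, q2 = q2, scope = scope),
             d$levels[g])
}

#' @export
total_mixture_effect.kmr_stratified <- function(fit, q1 = 0.5, q2 = 0.75,
                                                group = 1L,
                                                scope = "pooled") {
  g <- resolve_group(fit$dataset, group)
  eff <- total_mixture_effect.kmr(fit$fits[[g]], q1 = q1, q2 = q2,
                                  group = group, scope = scope,
                                  .dataset = fit$dataset)
  eff$group <- fit$levels[g]
  eff
}

#' Single-exposure effect
#'
#' Difference in expected outcome when exposure `m` moves from its `q1` to
#' its `q2` quantile while every other exposure is fixed at quantile `q`
#' (defaults: interquartile-range contrast at median conditioning).
#'
#' @inheritParams total_mixture_effect
#' @param m Exposure index (or name).
#' @param q Conditioning quantile for the other exposures.
#' @return A `kmr_effect`.
#' @export
single_exposure_effect <- function(fit, m, q1 = 0.25, q2 = 0.75, q = 0.5,
                                   group = 1L, scope = "pooled") {
  UseMethod("single_exposure_effect")
}

#' @export
single_exposure_effect.kmr <- function(fit, m, q1 = 0.25, q2 = 0.75, q = 0.5,
                                       group = 1L, scope = "pooled",
                                       .dataset = NULL) {
  d <- .dataset %||% fit$dataset
  if (is.character(m)) m <- match(m, d$names$exposures)
  if (is.na(m) || m < 1L || m > d$M) stop("invalid exposure index m")
  g <- resolve_group(d, group)
  gq <- if (fit$dataset$P == 1L) 1L else resolve_group(fit$dataset, group)
  base <- quantile_points(d, q, scope = scope, group = group)
  pa <- base; pa[m] <- quantile_points(d, q2, scope = scope, group = group)[m]
  pb <- base; pb[m] <- quantile_points(d, q1, scope = scope, group = group)[m]
  draws <- h_contrast_core(fit, rbind(pa, pb), c(gq, gq), 1L, 2L)
  new_effect(draws,
             list(kind = "single_exposure", m = m, q1 = q1, q2 = q2, q = q,
                  scope = scope),
             d$levels[g])
}

#' @export
single_exposure_effect.kmr_stratified <- function(fit, m, q1 = 0.25,
                                                  q2 = 0.75, q = 0.5,
                                                  group = 1L,
                                                  scope = "pooled") {
  g <- resolve_group(fit$dataset, group)
  eff <- single_exposure_effect.kmr(fit$fits[[g]], m = m, q1 = q1, q2 = q2,
                                    q = q, group = group, scope = scope,
                                    .dataset = fit$dataset)
  eff$group <- fit$levels[g]
  eff
}

#' Exposure-response curve for one exposure
#'
#' Posterior draws of the surface h along a grid of quantiles of exposure
#' `m`, the other exposures fixed at quantile `q`, for one group. Suitable
#' for ribbon plots of group-specific exposure-response functions.
#'
#' @inheritParams single_exposure_effect
#' @param grid Quantiles at which to evaluate the curve.
#' @return A data.frame of class `kmr_curve` with columns `quantile`,
#'   `exposure`, `mean`, `lower`, `upper`; the full draw matrix is attached
#'   as attribute `"draws"`.
#' @export
exposure_response_curve <- function(fit, m, grid = seq(0.25, 0.75, by = 0.05),
                                    q = 0.5, group = 1L, scope = "pooled") {
  UseMethod("exposure_response_curve")
}

#' @export
exposure_response_curve.kmr <- function(fit, m,
                                        grid = seq(0.25, 0.75, by = 0.05),
                                        q = 0.5, group = 1L,
                                        scope = "pooled", .dataset = NULL) {
  d <- .dataset %||% fit$dataset
  if (is.character(m)) m <- match(m, d$names$exposures)
  g <- resolve_group(d, group)
  gq <- if (fit$dataset$P == 1L) 1L else resolve_group(fit$dataset, group)
  if (fit$variant == "standard") gq <- 1L
  base <- quantile_points(d, q, scope = scope, group = group)
  qm <- vapply(grid, function(qq)
    quantile_points(d, qq, scope = scope, group = group)[m], numeric(1L))
  pts <- matrix(rep(base, each = length(grid)), nrow = length(grid))
  pts[, m] <- qm
  Zq <- apply_standardization(pts, d$std)
  h <- posterior_h_samples(fit, Zq, rep(gq, length(grid)),
                           seed_key = length(grid) + gq)
  out <- data.frame(quantile = grid, exposure = qm,
                    mean = colMeans(h),
                    lower = apply(h, 2L, stats::quantile, 0.025, type = 7),
                    upper = apply(h, 2L, stats::quantile, 0.975, type = 7))
  attr(out, "draws") <- h
  attr(out, "group") <- d$levels[g]
  class(out) <- c("kmr_curve", "data.frame")
  out
}

#' @export
exposure_response_curve.kmr_stratified <- function(fit, m,
    grid = seq(0.25, 0.75, by = 0.05), q = 0.5, group = 1L,
    scope = "pooled") {
  g <- resolve_group(fit$dataset, group)
  exposure_response_curve.kmr(fit$fits[[g]], m = m, grid = grid, q = q,
                              group = group, scope = scope,
                              .dataset = fit$dataset)
}

#' Between-group difference of two effect estimates
#'
#' Draw-wise difference of two effects of the same kind (first minus
#' second). For effects from a joint fit (`paired = TRUE`) this preserves
#' posterior dependence through the shared draws; for stratified fits
#' (`paired = FALSE`) independent chains are aligned by retained-draw order.
#'
#' @param effect_a,effect_b `kmr_effect` objects with matching query kind,
#'   quantiles and draw counts.
#' @param paired Whether the two effects share one posterior (joint fit).
#' @return A `kmr_effect` for the difference.
#' @export
between_group_difference <- function(effect_a, effect_b, paired = TRUE) {
  stopifnot(inherits(effect_a, "kmr_effect"), inherits(effect_b, "kmr_effect"))
  if (length(effect_a$draws) != length(effect_b$draws))
    stop("draw counts differ between effects")
  qa <- effect_a$query; qb <- effect_b$query
  same <- identical(qa[setdiff(names(qa), "scope")],
                    qb[setdiff(names(qb), "scope")])
  if (!same) stop("effects have different query kinds or quantiles")
  draws <- effect_a$draws - effect_b$draws
  query <- qa
  query$kind <- paste0("diff_", qa$kind)
  query$paired <- paired
  new_effect(draws, query, c(effect_a$group, effect_b$group))
}

#' Tabulate effect estimates
#'
#' @param effects A list of `kmr_effect` objects.
#' @return A data.frame with one row per effect (group, kind, quantiles,
#'   mean, lower, upper), suitable for CSV export.
#' @export
effect_table <- function(effects) {
  rows <- lapply(effects, function(e) {
    data.frame(group = paste(e$group, collapse = " - "),
               kind = e$query$kind,
               m = e$query$m %||% NA_integer_,
               q1 = e$query$q1, q2 = e$query$q2,
               q = e$query$q %||% NA_real_,
               mean = e$mean, lower = e$lower, upper = e$upper)
  })
  do.call(rbind, rows)
}
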