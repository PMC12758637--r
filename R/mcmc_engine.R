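#' Prior specification for kernel machine regression
#'
#' The model is fit on the scale `y ~ N(X beta, sigma2 * (I + lambda K))`
#' with `lambda = tau / sigma2` (one component per modifier group in the
#' group-separable variant) and `r_m = 1 / rho_m`. Priors: flat on `beta`,
#' inverse-gamma on `sigma2`, gamma on each `lambda`, independent uniform
#' `(0, r_max)` on each `r_m`.
#'
#' @param sigma_shape,sigma_rate Inverse-gamma shape/rate for `sigma2`.
#' @param lambda_shape,lambda_rate Gamma shape/rate for each `lambda`.
#' @param r_max Upper bound of the uniform prior on each inverse bandwidth.
#' @return A list of class `kmr_priors`.
#' @export
kmr_priors <- function(sigma_shape = 0.001, sigma_rate = 0.001,
                       lambda_shape = 1, lambda_rate = 0.1, r_max = 100) {
  vals <- c(sigma_shape, sigma_rate, lambda_shape, lambda_rate, r_max)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all prior hyperparameters must be positive and finite")
  structure(list(sigma_shape = sigma_shape, sigma_rate = sigma_rate,
                 lambda_shape = lambda_shape, lambda_rate = lambda_rate,
                 r_max = r_max),
            class = "kmr_priors")
}

#' MCMC run configuration
#'
#' @param iter Total iterations.
#' @param burnin Burn-in iterations discarded (must be < `iter`).
#' @param thin Thinning interval for retained draws.
#' @param sd_lambda,sd_r Random-walk proposal standard deviations on the
#'   sampling scale (log scale for lambda, natural scale for r).
#' @param adapt If `TRUE`, Robbins-Monro adaptation of proposal sds targeting
#'   0.44 acceptance, during burn-in only.
#' @param seed Optional integer seed; fixed seed + config gives bit-identical
#'   draws.
#' @param shared_tau Group-separable only: tie all lambda components to a
#'   single shared value.
#' @param verbose Print progress.
#' @return A list of class `kmr_control`.
#' @export
kmr_control <- function(iter = 10000, burnin = 5000, thin = 1,
                        sd_lambda = 0.3, sd_r = 0.3, adapt = TRUE,
                        seed = NULL, shared_tau = FALSE, verbose = FALSE) {
  if (burnin >= iter) stop("burnin must be smaller than iter")
  if (thin < 1) stop("thin must be >= 1")
  if (sd_lambda <= 0 || sd_r <= 0) stop("proposal sds must be > 0")
  structure(list(iter = as.integer(iter), burnin = as.integer(burnin),
                 thin = as.integer(thin), sd_lambda = sd_lambda, sd_r = sd_r,
                 adapt = isTRUE(adapt), seed = seed,
                 shared_tau = isTRUE(shared_tau), verbose = isTRUE(verbose)),
            class = "kmr_control")
}

# Design matrix for a variant: covariates plus (by default) modifier
# indicators whenever the dataset has P >= 2 groups.
kmr_design <- function(dataset, include_modifier = TRUE, reference = 1L) {
  X <- dataset$X
  if (include_modifier && dataset$P >= 2L) {
    enc <- encode_modifier(dataset$w, reference = reference)
    X <- cbind(X, enc$D)
  }
  X
}

# Internal block representation shared by all variants. The standard and
# modifier-in-kernel models are a single block over all rows; the
# group-separable model has one block per modifier group. Squared distances
# per kernel-input dimension are cached: only r = 1/rho moves during MCMC.
kmr_blocks <- function(dataset, variant, reference = 1L) {
  if (variant == "modifier_in_kernel") {
    enc <- encode_modifier(dataset$w, reference = reference)
    Zk <- cbind(dataset$Z, enc$D)
  } else {
    Zk <- dataset$Z
  }
  if (variant == "group_separable") {
    idx <- split(seq_len(dataset$n), dataset$w)
  } else {
    idx <- list(seq_len(dataset$n))
  }
  blocks <- lapply(idx, function(i) {
    list(idx = i, S = sqdist_list(Zk[i, , drop = FALSE]), n_g = length(i))
  })
  list(blocks = blocks, n_r = ncol(Zk), n_lambda = length(blocks), Zk = Zk)
}

# Cholesky factors of V_g = I + lambda_g K_g (+ jitter) for every block.
block_state <- function(bl, lambda, r) {
  lapply(seq_along(bl$blocks), function(g) {
    b <- bl$blocks[[g]]
    K <- kernel_from_sqdist(b$S, r)
    V <- lambda[g] * K
    diag(V) <- diag(V) + 1 + .kmr_jitter * lambda[g]
    R <- tryCatch(chol(V), error = function(e) {
      stop("covariance factorization failed (lambda = ",
           signif(lambda[g], 4), ", r = ", paste(signif(r, 4), collapse = ","),
           ")")
    })
    list(K = K, R = R)
  })
}

# Per-block contribution to log N(y; X beta, sigma2 * V), V = I + lambda K.
block_loglik <- function(resid_g, sigma2, R) {
  u <- backsolve(R, resid_g, transpose = TRUE)
  n_g <- length(resid_g)
  -0.5 * (n_g * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) +
            sum(u * u) / sigma2)
}

#' Marginal log-likelihood with the exposure-response surface integrated out
#'
#' Log density of the outcome under
#' `y ~ N(X beta, tau K + sigma2 I)` where `K` is the variant's kernel
#' (group-separable: block-diagonal with per-group `tau_g`). The
#' group-separable variant is evaluated block by block; results agree with a
#' dense evaluation to floating tolerance.
#'
#' @param dataset A `mixture_data`.
#' @param beta Covariate coefficient vector, conformable with `X` (see `X`).
#' @param sigma2 Positive residual variance.
#' @param params A [kernel_params()] object.
#' @param X Optional design matrix; defaults to the dataset covariates plus
#'   modifier indicators for the modifier-in-kernel and group-separable
#'   variants (matching [kmr()]'s default design).
#' @param reference Reference level for indicator encoding.
#' @return The log-likelihood (scalar).
#' @export
marginal_loglik <- function(dataset, beta, sigma2, params, X = NULL,
                            reference = 1L) {
  stopifnot(inherits(dataset, "mixture_data"), inherits(params, "kernel_params"))
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (is.null(X)) {
    X <- kmr_design(dataset,
                    include_modifier = params$variant != "standard",
                    reference = reference)
  }
  if (length(beta) != ncol(X)) stop("beta length does not match design matrix")
  bl <- kmr_blocks(dataset, params$variant, reference = reference)
  lambda <- rep(params$tau, length.out = bl$n_lambda) / sigma2
  if (params$variant == "group_separable" && length(params$tau) != bl$n_lambda)
    stop("tau must have one component per modifier group")
  if (length(params$rho) != bl$n_r)
    stop("rho length does not match the variant's kernel inputs")
  st <- block_state(bl, lambda, 1 / params$rho)
  resid <- dataset$y - drop(X %*% beta)
  ll <- 0
  for (g in seq_along(bl$blocks)) {
    ll <- ll + block_loglik(resid[bl$blocks[[g]]$idx], sigma2, st[[g]]$R)
  }
  ll
}

#' Conjugate draw of the covariate coefficients
#'
#' Samples `beta` from its full conditional under the flat prior:
#' `N((X' V^-1 X)^-1 X' V^-1 y, sigma2 (X' V^-1 X)^-1)` with
#' `V = I + lambda K`.
#'
#' @param y,X Outcome and design matrix.
#' @param sigma2 Current residual variance.
#' @param state Block Cholesky state (internal; see [kmr()]).
#' @param blocks Internal block structure.
#' @return A draw of `beta`.
#' @keywords internal
update_beta <- function(y, X, sigma2, state, blocks) {
  p <- ncol(X)
  A <- matrix(0, p, p)
  b <- numeric(p)
  for (g in seq_along(blocks$blocks)) {
    i <- blocks$blocks[[g]]$idx
    R <- state[[g]]$R
    UX <- backsolve(R, X[i, , drop = FALSE], transpose = TRUE)
    Uy <- backsolve(R, y[i], transpose = TRUE)
    A <- A + crossprod(UX)
    b <- b + drop(crossprod(UX, Uy))
  }
  RA <- tryCatch(chol(A), error = function(e) {
    qrX <- qr(X)
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  })
  mean_b <- backsolve(RA, backsolve(RA, b, transpose = TRUE))
  mean_b + sqrt(sigma2) * backsolve(RA, stats::rnorm(p))
}

#' Conjugate draw of the residual variance
#'
#' Samples `sigma2` from inverse-gamma(`a + n/2`,
#' `b + (y - X beta)' V^-1 (y - X beta) / 2`).
#'
#' @param resid Residual vector `y - X beta`.
#' @param state,blocks Internal block state.
#' @param priors A [kmr_priors()].
#' @return A draw of `sigma2`.
#' @keywords internal
update_sigma2 <- function(resid, state, blocks, priors) {
  quad <- 0
  for (g in seq_along(blocks$blocks)) {
    u <- backsolve(state[[g]]$R, resid[blocks$blocks[[g]]$idx],
                   transpose = TRUE)
    quad <- quad + sum(u * u)
  }
  n <- length(resid)
  1 / stats::rgamma(1L, shape = priors$sigma_shape + n / 2,
                    rate = priors$sigma_rate + quad / 2)
}

#' Gaussian random-walk Metropolis step
#'
#' One update of a scalar parameter. On the `"log"` scale the proposal is a
#' Gaussian step in `log(x)` and the acceptance ratio includes the Jacobian;
#' on the `"reflect"` scale the proposal is folded back into the support so
#' the kernel stays symmetric; `"identity"` is a plain unbounded random walk.
#' A uniform variate is always consumed, keeping the random-number stream
#' length independent of the accept/reject path.
#'
#' @param current Current value (must have finite `logpost`).
#' @param logpost Function returning the log posterior density at a value.
#' @param proposal_sd Proposal standard deviation on the sampling scale.
#' @param scale One of `"identity"`, `"log"`, `"reflect"`.
#' @param support Length-2 bounds, used by `"reflect"`.
#' @return List with `value` and `accepted` (logical).
#' @export
metropolis_update <- function(current, logpost, proposal_sd,
                              scale = c("identity", "log", "reflect"),
                              support = c(-Inf, Inf)) {
  scale <- match.arg(scale)
  lp0 <- logpost(current)
  if (is.nan(lp0)) stop("log posterior is NaN at the current value")
  step <- stats::rnorm(1L, 0, proposal_sd)
  jac <- 0
  if (scale == "log") {
    prop <- current * exp(step)
    jac <- log(prop) - log(current)  # d(log x) proposal on natural-scale density
  } else if (scale == "reflect") {
    prop <- reflect_into(current + step, support[1L], support[2L])
  } else {
    prop <- current + step
  }
  u <- stats::runif(1L)
  delta <- logpost(prop) - lp0 + jac
  if (is.finite(delta) && log(u) < delta) {
    list(value = prop, accepted = TRUE)
  } else {
    list(value = current, accepted = FALSE)
  }
}

reflect_into <- function(x, lo, hi) {
  width <- hi - lo
  if (!is.finite(width)) {
    if (is.finite(lo)) return(lo + abs(x - lo))
    if (is.finite(hi)) return(hi - abs(hi - x))
    return(x)
  }
  # fold into [lo, lo + 2*width) then mirror
  y <- (x - lo) %% (2 * width)
  lo + if (y > width) 2 * width - y else y
}

#' Fit a Bayesian kernel machine regression model
#'
#' Fits the hierarchical model `y = h(z) + x'beta + eps`,
#' `h ~ GP(0, tau K)`, `eps ~ N(0, sigma2)`, with the surface `h`
#' marginalized out, by MCMC: conjugate Gibbs draws for `beta` and `sigma2`
#' and random-walk Metropolis for each variance ratio `lambda = tau/sigma2`
#' (log scale) and each inverse bandwidth `r_m = 1/rho_m` (reflected at the
#' uniform prior bounds). Variants: `"standard"` (exposure-only kernel),
#' `"modifier_in_kernel"` (group indicators appended to the kernel inputs),
#' `"group_separable"` (block-diagonal kernel, one `lambda_g` per group,
#' shared `beta`, `sigma2` and bandwidths).
#'
#' @param dataset A [mixture_data()] object.
#' @param variant Model variant.
#' @param priors A [kmr_priors()].
#' @param control A [kmr_control()].
#' @param include_modifier_covariate Append modifier indicators to the
#'   covariate design matrix (default `TRUE` when P >= 2; the surface-based
#'   variants keep the group mean shift in the linear part).
#' @param reference Reference modifier level (internal code) for indicator
#'   encoding.
#' @return An object of class `kmr` holding retained draws (`beta`,
#'   `sigma2`, `lambda`, `r` matrices), the marginal log-likelihood
#'   trajectory, acceptance rates, the dataset, and run metadata.
#' @seealso [kmr_stratified()], [total_mixture_effect()],
#'   [diagnostics_report()]
#' @export
#' @examples
#' spec <- builtin_scenario("two_level_A")
#' spec$group_sizes <- c(30, 30)
#' d <- generate_dataset(spec)$dataset
#' fit <- kmr(d, variant = "group_separable",
#'            control = kmr_control(iter = 200, burnin = 100, seed = 1))
#' fit
kmr <- function(dataset,
                variant = c("standard", "modifier_in_kernel",
                            "group_separable"),
                priors = kmr_priors(), control = kmr_control(),
                include_modifier_covariate = TRUE, reference = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "mixture_data"),
            inherits(priors, "kmr_priors"), inherits(control, "kmr_control"))
  if (variant == "modifier_in_kernel" && dataset$P < 2L)
    stop("the modifier-in-kernel variant requires a modifier with P >= 2 ",
         "levels; use variant = 'standard'")
  if (!is.null(control$seed)) set.seed(control$seed)

  X <- kmr_design(dataset, include_modifier = include_modifier_covariate,
                  reference = reference)
  y <- dataset$y
  n <- dataset$n
  p <- ncol(X)
  bl <- kmr_blocks(dataset, variant, reference = reference)
  n_lam <- if (control$shared_tau && variant == "group_separable") 1L else bl$n_lambda

  # initial values: OLS beta, residual variance, prior-plausible lambda/r
  ols <- stats::lm.fit(X, y)
  beta <- ols$coefficients
  beta[is.na(beta)] <- 0
  sigma2 <- max(stats::var(ols$residuals), 1e-6)
  lambda <- rep(1, n_lam)
  r <- rep(0.5, bl$n_r)

  expand_lambda <- function(l) rep(l, length.out = bl$n_lambda)

  # cached per-block quantities: ACC = sum_m r_m S_m (flattened), the
  # correlation kernel K = exp(-ACC), and the Cholesky factor R of
  # I + lambda_g K (+ jitter); refreshed incrementally as parameters move
  make_block <- function(g, lam_g) {
    b <- bl$blocks[[g]]
    acc_g <- b$S[[1L]] * r[1L]
    if (bl$n_r > 1L) for (m in 2L:bl$n_r) acc_g <- acc_g + b$S[[m]] * r[m]
    K <- exp(-acc_g)
    V <- lam_g * K
    diag(V) <- diag(V) + 1 + .kmr_jitter * lam_g
    list(acc = acc_g, K = K, R = chol(V))
  }
  lamx <- expand_lambda(lambda)
  state <- lapply(seq_len(bl$n_lambda), function(g) make_block(g, lamx[g]))

  n_keep <- (control$iter - control$burnin) %/% control$thin
  draws <- list(
    beta = matrix(NA_real_, n_keep, p, dimnames = list(NULL, colnames(X))),
    sigma2 = numeric(n_keep),
    lambda = matrix(NA_real_, n_keep, n_lam),
    r = matrix(NA_real_, n_keep, bl$n_r),
    loglik = numeric(n_keep)
  )
  acc <- list(lambda = integer(n_lam), r = integer(bl$n_r))
  n_post <- 0L
  sd_lam <- rep(control$sd_lambda, n_lam)
  sd_r <- rep(control$sd_r, bl$n_r)
  ls_lam <- log(sd_lam); ls_r <- log(sd_r)

  lam_logprior <- function(x) {
    stats::dgamma(x, shape = priors$lambda_shape, rate = priors$lambda_rate,
                  log = TRUE)
  }
  keep_i <- 0L
  ll_g <- numeric(bl$n_lambda)
  for (it in seq_len(control$iter)) {
    in_burn <- it <= control$burnin

    beta <- update_beta(y, X, sigma2, state, bl)
    resid <- y - drop(X %*% beta)
    sigma2 <- update_sigma2(resid, state, bl, priors)
    for (g in seq_len(bl$n_lambda)) {
      ll_g[g] <- block_loglik(resid[bl$blocks[[g]]$idx], sigma2,
                              state[[g]]$R)
    }

    # lambda updates (log-scale random walk with Jacobian); only the
    # affected block(s) enter the ratio, and K is reused unchanged
    for (j in seq_len(n_lam)) {
      gset <- if (n_lam == bl$n_lambda) j else seq_len(bl$n_lambda)
      step <- stats::rnorm(1L, 0, exp(ls_lam[j]))
      u <- stats::runif(1L)
      prop <- lambda[j] * exp(step)
      if (!is.finite(prop) || prop <= 0) {
        if (!in_burn) acc$lambda[j] <- acc$lambda[j] + 0L
        if (in_burn && control$adapt)
          ls_lam[j] <- ls_lam[j] + (0 - 0.44) / it^0.6
        next
      }
      Rp <- vector("list", length(gset))
      llp <- numeric(length(gset))
      for (k in seq_along(gset)) {
        g <- gset[k]
        V <- prop * state[[g]]$K
        diag(V) <- diag(V) + 1 + .kmr_jitter * prop
        Rp[[k]] <- chol(V)
        llp[k] <- block_loglik(resid[bl$blocks[[g]]$idx], sigma2, Rp[[k]])
      }
      delta <- sum(llp) - sum(ll_g[gset]) +
        lam_logprior(prop) - lam_logprior(lambda[j]) +
        log(prop) - log(lambda[j])
      accepted <- is.finite(delta) && log(u) < delta
      if (accepted) {
        lambda[j] <- prop
        for (k in seq_along(gset)) {
          state[[gset[k]]]$R <- Rp[[k]]
          ll_g[gset[k]] <- llp[k]
        }
      }
      if (!in_burn) acc$lambda[j] <- acc$lambda[j] + accepted
      if (in_burn && control$adapt) {
        ls_lam[j] <- ls_lam[j] + (accepted - 0.44) / it^0.6
      }
    }

    # r updates: shared across blocks, every block kernel changes; the
    # weighted-distance accumulator makes a proposal a single pass per block
    lamx <- expand_lambda(lambda)
    for (m in seq_len(bl$n_r)) {
      step <- stats::rnorm(1L, 0, exp(ls_r[m]))
      u <- stats::runif(1L)
      prop <- reflect_into(r[m] + step, 0, priors$r_max)
      dlt <- prop - r[m]
      newb <- vector("list", bl$n_lambda)
      llp <- numeric(bl$n_lambda)
      for (g in seq_len(bl$n_lambda)) {
        b <- bl$blocks[[g]]
        acc_g <- state[[g]]$acc + dlt * b$S[[m]]
        K <- exp(-acc_g)
        V <- lamx[g] * K
        diag(V) <- diag(V) + 1 + .kmr_jitter * lamx[g]
        Rg <- chol(V)
        llp[g] <- block_loglik(resid[b$idx], sigma2, Rg)
        newb[[g]] <- list(acc = acc_g, K = K, R = Rg)
      }
      delta <- sum(llp) - sum(ll_g)
      accepted <- is.finite(delta) && log(u) < delta
      if (accepted) {
        r[m] <- prop
        state <- newb
        ll_g <- llp
      }
      if (!in_burn) acc$r[m] <- acc$r[m] + accepted
      if (in_burn && control$adapt) {
        ls_r[m] <- ls_r[m] + (accepted - 0.44) / it^0.6
      }
    }
    if (!in_burn) n_post <- n_post + 1L

    if (!in_burn && (it - control$burnin) %% control$thin == 0L) {
      keep_i <- keep_i + 1L
      draws$beta[keep_i, ] <- beta
      draws$sigma2[keep_i] <- sigma2
      draws$lambda[keep_i, ] <- lambda
      draws$r[keep_i, ] <- r
      draws$loglik[keep_i] <- sum(ll_g)
    }
    if (control$verbose && it %% 1000L == 0L)
      message("iteration ", it, "/", control$iter)
  }

  acc_rate <- list(lambda = acc$lambda / n_post, r = acc$r / n_post)
  if (any(unlist(acc_rate) == 0))
    warning("post-burn-in acceptance rate of 0 for at least one Metropolis ",
            "parameter; chains are degenerate")

  out <- list(
    draws = draws, acceptance = acc_rate, variant = variant,
    dataset = dataset, X = X, priors = priors, control = control,
    reference = reference,
    include_modifier_covariate = include_modifier_covariate,
    n_draws = n_keep
  )
  class(out) <- "kmr"
  out
}

#' Stratified kernel machine regression
#'
#' Fits an independent standard-variant model to each modifier subgroup.
#' Within a stratum the modifier carries no information, so indicators are
#' excluded from the covariates. Per-stratum seeds are derived
#' deterministically from `control$seed`, making each stratum reproducible
#' independently of fit order.
#'
#' @inheritParams kmr
#' @return An object of class `kmr_stratified`: a list of `kmr` fits (one
#'   per group, in internal level order) plus the full dataset.
#' @export
kmr_stratified <- function(dataset, priors = kmr_priors(),
                           control = kmr_control()) {
  stopifnot(inherits(dataset, "mixture_data"))
  if (dataset$P < 2L) stop("stratified fitting requires P >= 2 groups")
  p <- ncol(dataset$X)
  fits <- vector("list", dataset$P)
  for (g in seq_len(dataset$P)) {
    sub <- subset_mixture_data(dataset, dataset$w == g, drop_modifier = TRUE)
    if (sub$n <= p + 2L)
      stop("stratum '", dataset$levels[g], "' has too few observations (",
           sub$n, ") for ", p, " covariates")
    ctl <- control
    ctl$seed <- if (is.null(control$seed)) NULL else derive_seed(control$seed, g)
    fits[[g]] <- kmr(sub, variant = "standard", priors = priors,
                     control = ctl, include_modifier_covariate = FALSE)
  }
  structure(list(fits = fits, dataset = dataset, levels = dataset$levels,
                 control = control),
            class = "kmr_stratified")
}

# Row subset preserving class invariants; optionally drops the modifier
# (stratum-level data has a single group).
subset_mixture_data <- function(dataset, keep, drop_modifier = FALSE) {
  idx <- which(keep)
  d <- dataset
  d$y <- dataset$y[idx]
  d$Z <- dataset$Z[idx, , drop = FALSE]
  d$Z_orig <- dataset$Z_orig[idx, , drop = FALSE]
  d$X <- dataset$X[idx, , drop = FALSE]
  d$n <- length(idx)
  if (drop_modifier) {
    d$w <- rep.int(1L, d$n)
    d$levels <- "all"
    d$P <- 1L
    d$names$modifier <- NULL
  } else {
    d$w <- dataset$w[idx]
    present <- sort(unique(d$w))
    d$w <- match(d$w, present)
    d$levels <- dataset$levels[present]
    d$P <- length(present)
  }
  d
}

# deterministic sub-seed scheme; stays below 2^31 - 1
derive_seed <- function(master, counter) {
  as.integer(((as.double(master) %% 2147483647) * 69621 +
                10007 * as.double(counter)) %% 2147483647)
}
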