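# Shared fixtures and independent oracles for the test suite.

# small random study dataset built in code
tiny_dataset <- function(n = 24, M = 3, P = 2, seed = 1, n_cov = 1) {
  set.seed(seed)
  df <- data.frame(y = rnorm(n))
  for (m in seq_len(M)) df[[paste0("z", m)]] <- rexp(n) + 0.1
  covs <- character()
  for (j in seq_len(n_cov)) {
    nm <- paste0("x", j)
    df[[nm]] <- rnorm(n)
    covs <- c(covs, nm)
  }
  grp <- rep_len(paste0("g", seq_len(P)), n)
  df$grp <- if (P > 1) grp else NULL
  mixture_data(df, outcome = "y", exposures = paste0("z", seq_len(M)),
               covariates = covs, modifier = if (P > 1) "grp" else NULL)
}

fast_control <- function(iter = 200, burnin = 100, seed = 1, ...) {
  kmr_control(iter = iter, burnin = burnin, seed = seed, ...)
}

# a kmr object with fixed, replicated parameter draws (for conditioning
# oracles where hyperparameters are held at known values)
fixed_draw_fit <- function(dataset, variant, beta, sigma2, lambda, r,
                           n_draws = 50, seed = 99,
                           include_modifier_covariate = TRUE) {
  X <- gskmr:::kmr_design(dataset,
                          include_modifier = include_modifier_covariate)
  stopifnot(length(beta) == ncol(X))
  draws <- list(
    beta = matrix(beta, n_draws, length(beta), byrow = TRUE),
    sigma2 = rep(sigma2, n_draws),
    lambda = matrix(lambda, n_draws, length(lambda), byrow = TRUE),
    r = matrix(r, n_draws, length(r), byrow = TRUE),
    loglik = rep(NA_real_, n_draws)
  )
  colnames(draws$beta) <- colnames(X)
  structure(list(draws = draws,
                 acceptance = list(lambda = 1, r = 1),
                 variant = variant, dataset = dataset, X = X,
                 priors = kmr_priors(),
                 control = kmr_control(iter = 2, burnin = 1, seed = seed),
                 reference = 1L,
                 include_modifier_covariate = include_modifier_covariate,
                 n_draws = n_draws),
            class = "kmr")
}

# Independent dense multivariate-normal log-density: explicit covariance
# assembly with elementwise loops, generic solve() and determinant(); shares
# no code with the package's blocked Cholesky path. The documented
# 1e-8 * tau diagonal jitter is part of the model definition.
dense_marginal_loglik <- function(dataset, beta, sigma2, params, X) {
  n <- dataset$n
  Z <- dataset$Z
  w <- dataset$w
  Sigma <- matrix(0, n, n)
  if (params$variant == "modifier_in_kernel") {
    D <- matrix(0, n, dataset$P - 1L)
    lev <- sort(unique(w))[-1L]
    for (j in seq_along(lev)) D[, j] <- as.numeric(w == lev[j])
    ZD <- cbind(Z, D)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- 0
      for (m in seq_len(ncol(ZD)))
        s <- s + (ZD[i, m] - ZD[j, m])^2 / params$rho[m]
      Sigma[i, j] <- params$tau * exp(-s)
    }
    diag(Sigma) <- diag(Sigma) + 1e-8 * params$tau
  } else if (params$variant == "group_separable") {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (w[i] == w[j]) {
        s <- 0
        for (m in seq_len(dataset$M))
          s <- s + (Z[i, m] - Z[j, m])^2 / params$rho[m]
        Sigma[i, j] <- params$tau[w[i]] * exp(-s)
      }
    }
    diag(Sigma) <- diag(Sigma) + 1e-8 * params$tau[w]
  } else {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- 0
      for (m in seq_len(dataset$M))
        s <- s + (Z[i, m] - Z[j, m])^2 / params$rho[m]
      Sigma[i, j] <- params$tau * exp(-s)
    }
    diag(Sigma) <- diag(Sigma) + 1e-8 * params$tau
  }
  diag(Sigma) <- diag(Sigma) + sigma2
  resid <- dataset$y - as.vector(X %*% beta)
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  quad <- as.numeric(t(resid) %*% solve(Sigma, resid))
  -0.5 * (n * log(2 * pi) + ld + quad)
}

# random hyperparameters for oracle comparisons
random_params <- function(variant, M, P, seed) {
  set.seed(seed)
  rho_len <- if (variant == "modifier_in_kernel") M + P - 1L else M
  tau <- if (variant == "group_separable") runif(P, 0.2, 2) else runif(1, 0.2, 2)
  kernel_params(rho = runif(rho_len, 0.5, 5), tau = tau, variant = variant)
}
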