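#' Kernel hyperparameters
#'
#' Container for the smoothness vector `rho` and surface variance `tau` of a
#' kernel machine regression variant. For the standard and group-separable
#' variants `rho` has length M (one bandwidth per exposure); for
#' modifier-in-kernel it has length M + P - 1 (indicator dimensions included).
#' `tau` is a positive scalar except for the group-separable variant, where it
#' is a length-P vector with one surface variance per modifier group.
#'
#' @param rho Positive numeric vector of smoothness parameters.
#' @param tau Positive scalar (standard, modifier-in-kernel) or length-P
#'   vector (group-separable) of surface variances.
#' @param variant One of `"standard"`, `"modifier_in_kernel"`,
#'   `"group_separable"`.
#' @return An object of class `kernel_params`.
#' @export
kernel_params <- function(rho, tau,
                          variant = c("standard", "modifier_in_kernel",
                                      "group_separable")) {
  variant <- match.arg(variant)
  if (!all(is.finite(rho)) || any(rho <= 0)) stop("rho must be finite and > 0")
  if (!all(is.finite(tau)) || any(tau <= 0)) stop("tau must be finite and > 0")
  if (variant != "group_separable" && length(tau) != 1L)
    stop("tau must be scalar for variant '", variant, "'")
  structure(list(rho = as.numeric(rho), tau = as.numeric(tau),
                 variant = variant),
            class = "kernel_params")
}

#' Gaussian kernel matrix
#'
#' Computes the anisotropic Gaussian kernel
#' `K(z, z') = exp(-sum_m (z_m - z'_m)^2 / rho_m)` between the rows of two
#' exposure matrices.
#'
#' @param Z_a,Z_b Numeric matrices with M columns each.
#' @param rho Positive length-M vector of per-dimension smoothness parameters.
#' @return The `nrow(Z_a)` x `nrow(Z_b)` kernel matrix, entries in (0, 1].
#' @export
#' @examples
#' gaussian_kernel(matrix(0), matrix(2), rho = 4)  # exp(-1)
gaussian_kernel <- function(Z_a, Z_b, rho) {
  Z_a <- as.matrix(Z_a); Z_b <- as.matrix(Z_b)
  if (ncol(Z_a) != ncol(Z_b)) stop("exposure dimension mismatch")
  if (length(rho) != ncol(Z_a)) stop("rho length must equal ncol(Z)")
  if (any(!is.finite(rho)) || any(rho <= 0)) stop("rho must be finite and > 0")
  exp(-weighted_sqdist(Z_a, Z_b, 1 / rho))
}

# sum_m w_m * (z_am - z_bm)^2 for all row pairs, one BLAS-friendly pass
weighted_sqdist <- function(Z_a, Z_b, wts) {
  Aw <- sweep(Z_a, 2L, wts, "*")
  cross <- Aw %*% t(Z_b)
  a2 <- rowSums(Aw * Z_a)
  b2 <- rowSums(sweep(Z_b, 2L, wts, "*") * Z_b)
  d <- outer(a2, b2, "+") - 2 * cross
  d[d < 0] <- 0  # guard tiny negatives from cancellation
  d
}

# Per-dimension squared-distance matrices, cached once per fit: the MCMC
# moves rho but never the exposures, so K = exp(-sum_m r_m * S_m).
sqdist_list <- function(Z_a, Z_b = Z_a) {
  lapply(seq_len(ncol(Z_a)), function(m) {
    outer(Z_a[, m], Z_b[, m], "-")^2
  })
}

kernel_from_sqdist <- function(S, r) {
  acc <- S[[1L]] * r[1L]
  if (length(S) > 1L) for (m in 2L:length(S)) acc <- acc + S[[m]] * r[m]
  exp(-acc)
}

#' Modifier-in-kernel matrix
#'
#' Gaussian kernel over the column-concatenation of exposures and group
#' indicator variables, so that pairs in different groups are damped by the
#' indicator terms while same-group pairs are unaffected.
#'
#' @param Z_a,Z_b Exposure matrices (M columns).
#' @param D_a,D_b Indicator matrices (P-1 columns) from [encode_modifier()].
#' @param rho Positive vector of length M + P - 1: exposure bandwidths first,
#'   then one bandwidth per indicator column.
#' @return Kernel matrix of dimension `nrow(Z_a)` x `nrow(Z_b)`.
#' @export
modifier_in_kernel_matrix <- function(Z_a, D_a, Z_b, D_b, rho) {
  Z_a <- as.matrix(Z_a); Z_b <- as.matrix(Z_b)
  D_a <- as.matrix(D_a); D_b <- as.matrix(D_b)
  if (ncol(D_a) != ncol(D_b)) stop("indicator dimension mismatch")
  if (length(rho) != ncol(Z_a) + ncol(D_a))
    stop("rho must have length M + P - 1")
  gaussian_kernel(cbind(Z_a, D_a), cbind(Z_b, D_b), rho)
}

#' Group-separable kernel matrix
#'
#' Block-structured kernel: entries for pairs in the same modifier group g
#' equal `tau_g` times the Gaussian kernel of their exposures; entries for
#' pairs in different groups are exactly zero. Under a group-contiguous row
#' ordering the square kernel is block-diagonal with one tau_g-scaled
#' Gaussian block per group.
#'
#' @param Z_a,Z_b Exposure matrices (M columns).
#' @param w_a,w_b Integer group labels in `1..P` for the rows of `Z_a`, `Z_b`.
#' @param rho Positive length-M smoothness vector (shared across groups).
#' @param tau Positive length-P vector of group surface variances.
#' @return Kernel matrix of dimension `nrow(Z_a)` x `nrow(Z_b)`.
#' @export
group_separable_matrix <- function(Z_a, w_a, Z_b, w_b, rho, tau) {
  Z_a <- as.matrix(Z_a); Z_b <- as.matrix(Z_b)
  w_a <- as.integer(w_a); w_b <- as.integer(w_b)
  P <- length(tau)
  if (any(c(w_a, w_b) < 1L) || any(c(w_a, w_b) > P))
    stop("group label out of range 1..P")
  K <- matrix(0, nrow(Z_a), nrow(Z_b))
  for (g in seq_len(P)) {
    ia <- which(w_a == g); ib <- which(w_b == g)
    if (length(ia) && length(ib)) {
      K[ia, ib] <- tau[g] *
        gaussian_kernel(Z_a[ia, , drop = FALSE], Z_b[ib, , drop = FALSE], rho)
    }
  }
  K
}

#' Kernel and cross-kernel for query points under any variant
#'
#' Dispatches on the variant tag of `params` and returns the q x n
#' cross-kernel between query points and the training exposures together with
#' the q x q kernel among the query points, both on the tau (surface
#' variance) scale. Group-separable query points correlate only with
#' observations in their own group; the standard variant ignores group
#' labels.
#'
#' @param query q x M matrix of exposure values on the standardized scale
#'   used by the fit.
#' @param query_w Integer group labels for the query rows (required for the
#'   modifier-in-kernel and group-separable variants).
#' @param dataset A `mixture_data` object (training data).
#' @param params A [kernel_params()] object.
#' @param reference Reference level used for indicator encoding
#'   (modifier-in-kernel only); defaults to internal level 1.
#' @return List with `K_qn` (q x n) and `K_qq` (q x q).
#' @export
cross_kernel <- function(query, dataset, params, query_w = NULL,
                         reference = 1L) {
  stopifnot(inherits(dataset, "mixture_data"), inherits(params, "kernel_params"))
  query <- as.matrix(query)
  v <- params$variant
  if (v == "standard") {
    K_qn <- params$tau * gaussian_kernel(query, dataset$Z, params$rho)
    K_qq <- params$tau * gaussian_kernel(query, query, params$rho)
  } else if (v == "modifier_in_kernel") {
    if (is.null(query_w)) stop("query_w required for modifier_in_kernel")
    enc <- encode_modifier(dataset$w, reference = reference)
    D_q <- indicator_rows(query_w, enc)
    K_qn <- params$tau *
      modifier_in_kernel_matrix(query, D_q, dataset$Z, enc$D, params$rho)
    K_qq <- params$tau *
      modifier_in_kernel_matrix(query, D_q, query, D_q, params$rho)
  } else {
    if (is.null(query_w)) stop("query_w required for group_separable")
    K_qn <- group_separable_matrix(query, query_w, dataset$Z, dataset$w,
                                   params$rho, params$tau)
    K_qq <- group_separable_matrix(query, query_w, query, query_w,
                                   params$rho, params$tau)
  }
  list(K_qn = K_qn, K_qq = K_qq)
}

# indicator rows for arbitrary labels under an existing encoding
indicator_rows <- function(w, enc) {
  D <- matrix(0, length(w), length(enc$levels))
  for (j in seq_along(enc$levels)) D[, j] <- as.numeric(w == enc$levels[j])
  D
}

# diagonal jitter applied before factorizing square kernels
.kmr_jitter <- 1e-8
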