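# Structure-tensor -> control-tensor mapping. The magnitude is measured by
# repeated matrix squaring (a smooth proxy for the largest eigenvalue), the
# magnitude map is the M-function, and the shape map is an eigenvalue-free
# matrix polynomial whose scalar transfer has fixed points 0 and 1. A 2D
# eigendecomposition-based mapping is kept as the classical reference.

#' Mapping parameters
#'
#' @param alpha overshoot / transition parameter (>= 0, < 1 for the
#'   mu-function).
#' @param beta slope / softness parameter (> 0).
#' @param sigma soft noise threshold (>= 0), proportional to the SNR of the
#'   data.
#' @param mag_exponent even power-of-two exponent for the magnitude proxy
#'   (default 8).
#'
#' The defaults alpha = 0.55, beta = 1.5, sigma = 0.1 are the settings used
#' for the cardiac CT denoising.
#' @return an object of class `mapping_params`.
#' @export
mapping_params <- function(alpha = 0.55, beta = 1.5, sigma = 0.1,
                           mag_exponent = 8L) {
  if (alpha < 0) stop("alpha must be >= 0")
  if (beta <= 0) stop("beta must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  e <- as.integer(mag_exponent)
  if (e < 1L || bitwAnd(e, e - 1L) != 0L) stop("mag_exponent must be a power of 2")
  structure(list(alpha = alpha, beta = beta, sigma = sigma, mag_exponent = e),
            class = "mapping_params")
}

#' M-function: map the normalized tensor magnitude
#'
#' `gamma = gamma0^beta / (gamma0^(alpha+beta) + sigma^beta)`. sigma acts
#' as a soft noise threshold, alpha controls the overshoot (values slightly
#' above the noise floor can be amplified beyond 1) and beta the slope.
#'
#' @param gamma0 normalized magnitudes in \[0, 1\] (vector or array).
#' @param params a [mapping_params()].
#' @return mapped magnitudes `gamma` (>= 0).
#' @export
m_function <- function(gamma0, params = mapping_params()) {
  if (any(!is.finite(gamma0)) || any(gamma0 < -1e-12 | gamma0 > 1 + 1e-12)) {
    stop("gamma0 must lie in [0, 1]")
  }
  gamma0 <- pmin(pmax(gamma0, 0), 1)
  out <- gamma0
  pos <- gamma0 > 0
  out[!pos] <- 0
  g <- gamma0[pos]
  out[pos] <- g^params$beta / (g^(params$alpha + params$beta) + params$sigma^params$beta)
  out
}

#' mu-function: map the tensor isotropy
#'
#' `phi = (phi0 (1-alpha))^beta / ((phi0 (1-alpha))^beta + (alpha (1-phi0))^beta)`,
#' a monotone map of the eigenvalue ratio phi0 = lambda2/lambda1 that makes
#' nearly isotropic tensors more isotropic and anisotropic ones more
#' anisotropic; `mu(alpha) = 1/2` for every beta.
#'
#' @param phi0 isotropy values in \[0, 1\].
#' @param alpha transition parameter in (0, 1).
#' @param beta slope parameter (> 0).
#' @return mapped isotropy values in \[0, 1\].
#' @export
mu_function <- function(phi0, alpha = 0.55, beta = 1.5) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (beta <= 0) stop("beta must be > 0")
  if (any(!is.finite(phi0)) || any(phi0 < 0 | phi0 > 1)) stop("phi0 must lie in [0, 1]")
  a <- (phi0 * (1 - alpha))^beta
  b <- (alpha * (1 - phi0))^beta
  a / (a + b)
}

# Componentwise product of two commuting symmetric matrices stored as
# (n_voxels x n_components) matrices; only the upper triangle is formed.
sym_mult <- function(A, B, d) {
  L <- comp_lookup(d)
  p <- comp_pairs(d)
  out <- matrix(0, nrow(A), ncol(A))
  for (c in seq_len(nrow(p))) {
    i <- p[c, 1L]; j <- p[c, 2L]
    acc <- A[, L[i, 1L]] * B[, L[1L, j]]
    for (k in 2:d) acc <- acc + A[, L[i, k]] * B[, L[k, j]]
    out[, c] <- acc
  }
  out
}

sym_add_identity <- function(A, d, scale = 1) {
  p <- comp_pairs(d)
  diag_c <- which(p[, 1L] == p[, 2L])
  A[, diag_c] <- A[, diag_c] + scale
  A
}

sym_frobenius2 <- function(A, d) {
  p <- comp_pairs(d)
  w <- ifelse(p[, 1L] == p[, 2L], 1, 2)
  as.vector(A^2 %*% w)
}

#' Tensor magnitude by repeated matrix squaring
#'
#' `T_mag = ||T^e||_F^(1/e)` with `T^e` built by repeated squaring
#' (`T2 = T*T, T4 = T2*T2, ...`); for e = 8 this lies within
#' `[lambda1, 4^(1/16) lambda1]` for a PSD 4x4 tensor, i.e. it is a smooth
#' eigenvalue-free proxy for the largest eigenvalue. `gamma0` is the
#' magnitude normalized by its maximum over the dataset.
#'
#' @param tf a `tensor_field4d`.
#' @param exponent power-of-two exponent (default 8).
#' @param norm_max optional externally supplied dataset maximum of `T_mag`
#'   (used by the two-pass slab scheme); `NULL` uses the field's own max.
#' @return an object of class `magnitude_field`: list with `t_mag`,
#'   `gamma0` (arrays) and `max_t_mag`.
#' @export
tensor_magnitude <- function(tf, exponent = 8L, norm_max = NULL) {
  exponent <- as.integer(exponent)
  if (exponent < 1L || bitwAnd(exponent, exponent - 1L) != 0L) {
    stop("exponent must be a power of 2")
  }
  d <- tf$dim
  M <- tensor_as_matrix(tf)
  P <- M
  for (s in seq_len(as.integer(log2(exponent)))) P <- sym_mult(P, P, d)
  t_mag <- sym_frobenius2(P, d)^(1 / (2 * exponent))
  mx <- if (is.null(norm_max)) max(t_mag) else norm_max
  gamma0 <- if (mx > 0) pmin(t_mag / mx, 1) else t_mag * 0
  structure(
    list(t_mag = array(t_mag, tf$extent), gamma0 = array(gamma0, tf$extent),
         max_t_mag = mx),
    class = "magnitude_field"
  )
}

#' Scalar transfer function of the eigenvalue-free shape mapping
#'
#' The shape mapping acts on each eigenvalue of the normalized tensor as
#' `f(lambda) = 1 - (1 - g)^8 (1 + 8 g)` with the smoothstep
#' `g(lambda) = lambda^2 (3 - 2 lambda)`. Fixed points 0 and 1; small
#' eigenvalues shrink, large ones grow. Used as the oracle for
#' [control_tensor()].
#'
#' @param lambda eigenvalues (vector or array).
#' @return mapped eigenvalues.
#' @export
eigen_transfer <- function(lambda) {
  g <- lambda^2 * (3 - 2 * lambda)
  1 - (1 - g)^8 * (1 + 8 * g)
}

#' Eigenvalue-free shape mapping of a normalized tensor field
#'
#' Matrix-polynomial form of [eigen_transfer()] applied to a field of
#' normalized tensors That: `That_f = That^2 (I + 2 (I - That))` followed by
#' `I - (I - That_f)^8 (I + 8 That_f)` with all powers by repeated
#' multiplication. Shares the eigensystem of That and maps each eigenvalue
#' through the scalar transfer.
#'
#' @param That (n_voxels x n_components) matrix of normalized tensors.
#' @param d tensor dimensionality.
#' @return matrix of the same shape.
#' @export
map_tensor_shape <- function(That, d) {
  S2 <- sym_mult(That, That, d)
  S3 <- sym_mult(S2, That, d)
  Tf <- 3 * S2 - 2 * S3
  Mm <- sym_add_identity(-Tf, d)          # I - That_f
  M2 <- sym_mult(Mm, Mm, d)
  M4 <- sym_mult(M2, M2, d)
  M8 <- sym_mult(M4, M4, d)
  B <- sym_add_identity(8 * Tf, d)        # I + 8 That_f
  sym_add_identity(-sym_mult(M8, B, d), d)
}

#' Map a structure tensor field to the control tensor field
#'
#' Normalizes each tensor by its magnitude (`That = T / T_mag`), applies the
#' eigenvalue-free shape mapping, and scales by the mapped magnitude
#' `gamma = M(gamma0)`. Voxels with negligible magnitude
#' (`T_mag <= eps_rel * max`) get a zero control tensor: such neighbourhoods
#' are treated as pure noise and receive only lowpass output.
#'
#' @param tf a (smoothed) `tensor_field4d`.
#' @param mag a `magnitude_field` from [tensor_magnitude()].
#' @param params a [mapping_params()].
#' @param eps_rel relative magnitude floor below which the mapping is
#'   skipped.
#' @return an object of class `control_tensor_field`: `components` (named
#'   list, same layout as the structure tensor), `gamma`, `dim`, `extent`,
#'   `valid`.
#' @export
control_tensor <- function(tf, mag, params = mapping_params(), eps_rel = 1e-12) {
  d <- tf$dim
  M <- tensor_as_matrix(tf)
  t_mag <- as.vector(mag$t_mag)
  gamma <- as.vector(m_function(mag$gamma0, params))
  eps <- eps_rel * max(mag$max_t_mag, max(t_mag))
  ok <- t_mag > eps
  That <- M * 0
  That[ok, ] <- M[ok, , drop = FALSE] / t_mag[ok]
  C <- map_tensor_shape(That, d) * gamma
  C[!ok, ] <- 0
  comps <- lapply(seq_len(ncol(C)), function(c) array(C[, c], tf$extent))
  names(comps) <- names(tf$components)
  structure(
    list(components = comps, gamma = array(gamma, tf$extent), dim = d,
         extent = tf$extent, valid = tf$valid),
    class = "control_tensor_field"
  )
}

#' Classical 2D control-tensor mapping (eigendecomposition reference)
#'
#' For a single symmetric PSD 2x2 tensor: eigendecompose, map the magnitude
#' `gamma0 = sqrt(lambda1^2 + lambda2^2)` (assumed already normalized to
#' \[0, 1\] over the dataset) with the M-function and the isotropy
#' `phi0 = lambda2/lambda1` with the mu-function, and rebuild
#' `C = gamma e1 e1' + gamma phi e2 e2'`.
#'
#' @param T symmetric 2x2 matrix (PSD).
#' @param params a [mapping_params()].
#' @param gamma0 optional override for the normalized magnitude.
#' @return the mapped 2x2 control tensor.
#' @export
control_tensor_2d <- function(T, params = mapping_params(), gamma0 = NULL) {
  if (!isTRUE(all.equal(T, t(T)))) stop("T must be symmetric")
  e <- eigen(T, symmetric = TRUE)
  l1 <- e$values[1L]; l2 <- e$values[2L]
  if (l1 < -1e-12) stop("T must be positive semidefinite")
  if (l1 <= 0) return(matrix(0, 2L, 2L))
  if (is.null(gamma0)) gamma0 <- sqrt(l1^2 + l2^2)
  if (gamma0 > 1 + 1e-12) stop("gamma0 exceeds 1; normalize the magnitude first")
  gam <- m_function(min(gamma0, 1), params)
  phi <- mu_function(max(l2, 0) / l1, params$alpha, params$beta)
  e1 <- e$vectors[, 1L]; e2 <- e$vectors[, 2L]
  gam * tcrossprod(e1) + gam * phi * tcrossprod(e2)
}
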