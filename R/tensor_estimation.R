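# Structure tensor estimation: apply the monomial bank, combine the
# responses into the unique components of the symmetric structure tensor,
# and smooth the tensor field with certainty weighting.

#' Apply a monomial filter bank to a volume
#'
#' Produces one real response field per bank member, in the fixed order
#' first-order (x, y, z, t) then second-order (xx, xy, ..., tt). The
#' `"fft"` backend multiplies by the exact ideal frequency responses; the
#' `"spatial"` backend applies the windowed kernels (evaluated as circular
#' correlation through the FFT, identical to the direct primitive).
#'
#' @param vol a [volume4d()].
#' @param bank a monomial `filter_bank` (see [build_monomial_bank()]).
#' @param backend `"fft"` or `"spatial"`.
#' @return an object of class `monomial_responses`: list with `responses`
#'   (named list of arrays), `dim`, `extent`, `valid`.
#' @export
apply_monomial_bank <- function(vol, bank, backend = c("fft", "spatial")) {
  backend <- match.arg(backend)
  vol <- as_volume4d(vol)
  ext <- dim(vol$values)
  if (bank$type != "monomial") stop("bank must be a monomial bank")
  if (backend == "spatial") {
    supp <- vapply(bank$kernels, function(k) max(dim(k$values)), 0L)
    if (any(max(supp) > ext[seq_len(bank$dim)])) {
      stop("volume extent smaller than kernel support on an active axis")
    }
  }
  H <- backend_responses(bank, ext, backend)
  resp <- apply_responses_fft(vol$values, H)
  nm <- c(axis_names4[seq_len(bank$dim)], comp_names(bank$dim))
  names(resp) <- nm
  valid <- vol$valid
  if (backend == "spatial") {
    # z margin of the nonseparable support (x, y, t circular in the core)
    r <- (bank$support - 1L) %/% 2L
    if (ext[3L] > 1L) valid <- shrink_valid(valid, 3L, r)
  }
  structure(
    list(responses = resp, dim = bank$dim, extent = ext, valid = valid),
    class = "monomial_responses"
  )
}

#' Assemble the structure tensor from monomial responses
#'
#' Pointwise combination `T = Q1 Q1' + Q2 Q2'` where Q1 holds the
#' first-order responses and Q2 the symmetric matrix of second-order
#' responses: `t_ij = fr_i fr_j + sum_k Q2[i,k] Q2[k,j]`. For 4D this
#' expands to the familiar 10-component formulas (e.g.
#' `t1 = fr1^2 + fr5^2 + fr6^2 + fr7^2 + fr8^2`).
#'
#' @param resp a `monomial_responses` object.
#' @return an object of class `tensor_field4d`: list with `components`
#'   (named list, upper-triangle row-major order), `dim`, `extent`, `valid`.
#' @export
assemble_tensor <- function(resp) {
  d <- resp$dim
  L <- comp_lookup(d)
  p <- comp_pairs(d)
  q1 <- resp$responses[seq_len(d)]
  q2 <- resp$responses[d + seq_len(nrow(p))]
  comps <- vector("list", nrow(p))
  for (c in seq_len(nrow(p))) {
    i <- p[c, 1L]; j <- p[c, 2L]
    acc <- q1[[i]] * q1[[j]]
    for (k in seq_len(d)) acc <- acc + q2[[L[i, k]]] * q2[[L[k, j]]]
    comps[[c]] <- acc
  }
  names(comps) <- comp_names(d)
  structure(
    list(components = comps, dim = d, extent = resp$extent, valid = resp$valid),
    class = "tensor_field4d"
  )
}

# smoothing kernels for the tensor / control-tensor lowpass: normalized
# binomial weights, 5 taps on x, y, z and 3 on t (the 5x5x5x3 stage)
tensor_smoothing_kernels <- function(extent) {
  b5 <- c(1, 4, 6, 4, 1) / 16
  b3 <- c(1, 2, 1) / 4
  lapply(1:4, function(a) {
    if (extent[a] == 1L) NULL else if (a == 4L) b3 else b5
  })
}

#' Smooth a tensor field componentwise
#'
#' Separable binomial lowpass of size 5x5x5x3 applied to every tensor
#' component, with normalized convolution when a certainty is supplied
#' (symmetry is preserved trivially since the filtering is componentwise).
#'
#' @param tf a `tensor_field4d` (or a control tensor field).
#' @param cert optional certainty array in \[0, 1\]; `NULL` means plain
#'   filtering (full certainty).
#' @param modes per-axis boundary mode as in [separable_conv()]; default
#'   all-circular.
#' @return the smoothed field, same class and layout.
#' @export
smooth_tensor <- function(tf, cert = NULL, modes = "circular") {
  kern <- tensor_smoothing_kernels(tf$extent)
  den <- NULL
  if (!is.null(cert)) {
    cert <- as_dim4(cert)
    if (!identical(dim(cert), tf$extent)) stop("certainty shape mismatch")
    den <- separable_conv(volume4d(cert), kern, modes)$values
    if (any(den <= 0)) stop("certainty support vanishes under the smoothing kernel")
  }
  sm <- function(x) {
    if (is.null(cert)) {
      separable_conv(volume4d(x), kern, modes)$values
    } else {
      separable_conv(volume4d(x * cert), kern, modes)$values / den
    }
  }
  tf$components <- lapply(tf$components, sm)
  if (!is.null(tf$gamma)) tf$gamma <- sm(tf$gamma)
  tf
}

# Tensor field <-> (n_voxels x n_components) matrix used by the mapping
# module.
tensor_as_matrix <- function(tf) {
  do.call(cbind, lapply(tf$components, as.vector))
}

matrix_as_tensor <- function(M, template) {
  comps <- lapply(seq_len(ncol(M)), function(c) array(M[, c], template$extent))
  names(comps) <- names(template$components)
  out <- template
  out$components <- comps
  out
}
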