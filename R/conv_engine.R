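# Filtering primitives: separable and direct nonseparable correlation,
# FFT-based circular filtering, normalized convolution, and the
# valid-region bookkeeping that mirrors the slab-processing arithmetic.

normalize_modes <- function(modes, vol = NULL) {
  if (is.null(modes)) {
    modes <- c("circular", "circular", "valid", "circular")
    if (!is.null(vol) && !vol$periodic_t) modes[4L] <- "valid"
  }
  if (length(modes) == 1L) modes <- rep(modes, 4L)
  if (!all(modes %in% c("circular", "valid"))) stop("modes must be 'circular' or 'valid'")
  modes
}

#' Separable spatial correlation
#'
#' Sequential per-axis 1D correlation with odd-length kernels. Values are
#' computed with circular index arithmetic on every axis; on axes in
#' `"valid"` mode the valid interval is shrunk by the kernel half-width
#' (inside the shrunk interval circular and zero-padded results coincide).
#'
#' @param vol a [volume4d()].
#' @param kernels list of four numeric vectors (odd length) or `NULL` to
#'   skip an axis.
#' @param modes per-axis boundary mode, `"circular"` or `"valid"`; default
#'   circular in x, y, t (t following `periodic_t`) and valid in z.
#' @return a `volume4d` with updated valid intervals.
#' @export
separable_conv <- function(vol, kernels, modes = NULL) {
  vol <- as_volume4d(vol)
  modes <- normalize_modes(modes, vol)
  a <- vol$values
  valid <- vol$valid
  for (axis in 1:4) {
    k <- kernels[[axis]]
    if (is.null(k) || (length(k) == 1L && k[1L] == 1)) next
    if (length(k) %% 2L == 0L) stop("kernel length must be odd (axis ", axis, ")")
    r <- (length(k) - 1L) %/% 2L
    if (modes[axis] == "valid" && length(k) > dim(a)[axis]) {
      stop("kernel longer than axis ", axis, " in valid mode")
    }
    acc <- array(0, dim(a))
    for (j in seq_along(k)) {
      if (k[j] == 0) next
      acc <- acc + k[j] * shift_axis(a, axis, j - r - 1L)
    }
    a <- acc
    if (modes[axis] == "valid") valid <- shrink_valid(valid, axis, r)
  }
  volume4d(a, spacing = vol$spacing, valid = valid, periodic_t = vol$periodic_t)
}

#' Direct nonseparable nD correlation
#'
#' Plain correlation `out(x) = sum_u k(u) s(x + u)` with the kernel centred
#' on its middle sample. Values use circular index arithmetic; `"valid"`
#' axes shrink the valid interval by the kernel half-width. This is the
#' reference primitive: the pipeline evaluates the same circular correlation
#' through the FFT for speed.
#'
#' @param vol a [volume4d()].
#' @param kernel a `filter_kernel` or a numeric array with odd extents.
#' @param modes per-axis boundary mode as in [separable_conv()].
#' @return a `volume4d`.
#' @export
nonseparable_conv <- function(vol, kernel, modes = NULL) {
  vol <- as_volume4d(vol)
  modes <- normalize_modes(modes, vol)
  k <- if (inherits(kernel, "filter_kernel")) kernel$values else as_dim4(kernel)
  kd <- dim(k)
  if (any(kd %% 2L == 0L)) stop("kernel support must be odd per axis")
  ext <- dim(vol$values)
  r <- (kd - 1L) %/% 2L
  for (axis in 1:4) {
    if (modes[axis] == "valid" && kd[axis] > ext[axis]) {
      stop("kernel longer than axis ", axis, " in valid mode")
    }
  }
  out <- array(0, ext)
  idx <- which(k != 0, arr.ind = TRUE)
  for (row in seq_len(nrow(idx))) {
    off <- idx[row, ] - r - 1L
    out <- out + k[idx[row, 1L], idx[row, 2L], idx[row, 3L], idx[row, 4L]] *
      shift4(vol$values, off)
  }
  valid <- vol$valid
  for (axis in 1:4) {
    if (modes[axis] == "valid") valid <- shrink_valid(valid, axis, r[axis])
  }
  volume4d(out, spacing = vol$spacing, valid = valid, periodic_t = vol$periodic_t)
}

# Embed a correlation-oriented kernel into a full-size array so that
# multiplying by its DFT performs circular correlation with the centred
# kernel (the convolution-theorem layout of the flipped kernel). Kernels
# longer than an axis are folded modulo the axis length, matching direct
# circular correlation with repeated wrap-around.
pad_kernel_for_correlation <- function(kernel, extent) {
  k <- if (inherits(kernel, "filter_kernel")) kernel$values else as_dim4(kernel)
  out <- reverse_all(k)            # correlation = convolution with flip
  for (a in 1:4) {
    kd <- dim(out)[a]
    n <- extent[a]
    r <- (kd - 1L) %/% 2L
    td <- dim(out)
    td[a] <- n
    tmp <- array(0, td)
    for (j in seq_len(kd)) {
      pos <- ((j - 1L - r) %% n) + 1L
      sl <- index_axis(out, a, j)
      tmp <- switch(a,
        { tmp[pos, , , ] <- tmp[pos, , , , drop = FALSE] + sl; tmp },
        { tmp[, pos, , ] <- tmp[, pos, , , drop = FALSE] + sl; tmp },
        { tmp[, , pos, ] <- tmp[, , pos, , drop = FALSE] + sl; tmp },
        { tmp[, , , pos] <- tmp[, , , pos, drop = FALSE] + sl; tmp })
    }
    out <- tmp
  }
  out
}

#' FFT-based circular filtering
#'
#' Circular filtering on all four axes: forward 4D transform, pointwise
#' complex multiplication, inverse transform, real part. The filter can be
#' given either as a full-grid frequency response (applied as-is, the ideal
#' path) or as a small spatial kernel, which is zero-padded and centre
#' shifted so that the result equals circular correlation with the centred
#' kernel.
#'
#' @param vol a [volume4d()].
#' @param filt frequency response array matching the volume extent, or a
#'   `filter_kernel` / small odd-support array.
#' @param type disambiguates `filt`: `"auto"` treats a `filter_kernel` or a
#'   smaller array as a spatial kernel and a full-extent array as a
#'   frequency response.
#' @return a `volume4d` with full-extent valid intervals (circular).
#' @export
fft_filter <- function(vol, filt, type = c("auto", "response", "kernel")) {
  type <- match.arg(type)
  vol <- as_volume4d(vol)
  ext <- dim(vol$values)
  is_kern <- inherits(filt, "filter_kernel")
  fa <- if (is_kern) filt$values else as_dim4(filt)
  if (type == "auto") {
    type <- if (!is_kern && identical(dim(fa), ext)) "response" else "kernel"
  }
  if (type == "kernel") {
    H <- stats::fft(pad_kernel_for_correlation(fa, ext))
  } else {
    if (!identical(dim(fa), ext)) stop("frequency response shape mismatch")
    H <- fa
  }
  out <- Re(stats::fft(stats::fft(vol$values) * H, inverse = TRUE)) / prod(ext)
  volume4d(out, spacing = vol$spacing, periodic_t = vol$periodic_t)
}

# Apply a list of frequency responses with one forward FFT, packing filter
# pairs into the real and imaginary parts of a single inverse transform
# (valid because the signal and all spatial kernels are real).
apply_responses_fft <- function(values, responses) {
  ext <- dim(values)
  Fv <- stats::fft(values)
  n <- length(responses)
  out <- vector("list", n)
  i <- 1L
  while (i <= n) {
    if (i < n) {
      r <- stats::fft(Fv * (responses[[i]] + 1i * responses[[i + 1L]]), inverse = TRUE) /
        prod(ext)
      out[[i]] <- Re(r)
      out[[i + 1L]] <- Im(r)
      i <- i + 2L
    } else {
      out[[i]] <- Re(stats::fft(Fv * responses[[i]], inverse = TRUE)) / prod(ext)
      i <- i + 1L
    }
  }
  out
}

# Responses used by a backend for a bank on a given extent: exact ideal
# responses for the FFT backend, DFTs of the padded windowed kernels for
# the spatial backend.
backend_responses <- function(bank, extent, backend) {
  if (backend == "fft") {
    bank_frequency_responses(bank, extent)
  } else {
    lapply(bank$kernels, function(k) stats::fft(pad_kernel_for_correlation(k, extent)))
  }
}

#' Normalized convolution (normalized averaging)
#'
#' Certainty-weighted filtering `((c * s) conv f) / (c conv f)`: border or
#' missing samples carry certainty 0 and are renormalized away instead of
#' darkening the result. Only valid for nonnegative filters.
#'
#' @param vol a [volume4d()] (the signal s).
#' @param cert certainty array with values in \[0, 1\], same extent as the
#'   signal.
#' @param kernels either a list of four 1D kernels (separable path) or a
#'   nonnegative nD array.
#' @param modes per-axis boundary mode as in [separable_conv()].
#' @param eps_rel denominators at or below `eps_rel * sum(f)` are marked
#'   undefined (scale-invariant guard).
#' @return a `volume4d` with an extra logical element `defined`; undefined
#'   voxels hold 0. An all-zero certainty yields an all-undefined output.
#' @export
normalized_conv <- function(vol, cert, kernels, modes = NULL, eps_rel = 1e-12) {
  vol <- as_volume4d(vol)
  cert <- as_dim4(cert)
  if (!identical(dim(cert), dim(vol$values))) stop("certainty shape mismatch")
  if (any(cert < 0 | cert > 1)) stop("certainty must lie in [0, 1]")
  separable <- is.list(kernels)
  ksum <- if (separable) {
    prod(vapply(kernels, function(k) if (is.null(k)) 1 else sum(k), 0))
  } else {
    sum(kernels)
  }
  if (separable) {
    for (k in kernels) if (!is.null(k) && any(k < 0)) stop("kernel must be nonnegative")
  } else if (any(kernels < 0)) stop("kernel must be nonnegative")
  if (ksum <= 0) stop("kernel must have positive sum")

  conv1 <- function(x) {
    v <- volume4d(x, spacing = vol$spacing, periodic_t = vol$periodic_t)
    if (separable) separable_conv(v, kernels, modes) else nonseparable_conv(v, kernels, modes)
  }
  num <- conv1(vol$values * cert)
  den <- conv1(cert)
  eps <- eps_rel * ksum
  defined <- den$values > eps
  out <- array(0, dim(vol$values))
  out[defined] <- num$values[defined] / den$values[defined]
  res <- volume4d(out, spacing = vol$spacing, valid = num$valid,
                  periodic_t = vol$periodic_t)
  res$defined <- defined
  res
}

#' Valid-slice bookkeeping through the denoising chain
#'
#' Propagates the number of valid z-slices through the fixed processing
#' chain: 3x3x3 lowpass (loses 2 with standard convolution, none with
#' normalized convolution), downsample by 2 (ceiling), 7^4 monomial
#' filtering (loses 6 at half resolution), 5x5x5x3 tensor lowpass and
#' 5x5x5x3 control-tensor lowpass (4 each with standard convolution, none
#' with normalized convolution), then full-resolution coverage
#' `2 * (half_valid - 1) + 1` capped by the 11^4 reconstruction margin
#' `n - 10`. Counts floor at zero.
#'
#' @param n_slices number of input z-slices (>= 1).
#' @param use_normalized_conv do the separable lowpass stages use
#'   normalized convolution?
#' @return a list of per-stage counts: `input`, `after_lowpass`,
#'   `after_downsample`, `after_monomial`, `after_tensor_lowpass`,
#'   `after_control_lowpass`, `coverage`, `final_output`.
#' @export
plan_valid_slices <- function(n_slices, use_normalized_conv = TRUE) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) stop("n_slices must be >= 1")
  f0 <- function(x) max(0L, x)
  lp <- if (use_normalized_conv) n_slices else f0(n_slices - 2L)
  ds <- as.integer(ceiling(lp / 2))
  mono <- f0(ds - 6L)
  tlp <- if (use_normalized_conv) mono else f0(mono - 4L)
  clp <- if (use_normalized_conv) tlp else f0(tlp - 4L)
  cov <- if (clp >= 1L) 2L * (clp - 1L) + 1L else 0L
  fin <- f0(min(cov, n_slices - 10L))
  list(input = n_slices, after_lowpass = lp, after_downsample = ds,
       after_monomial = mono, after_tensor_lowpass = tlp,
       after_control_lowpass = clp, coverage = cov, final_output = fin)
}
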