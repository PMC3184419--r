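# Filter bank construction: lognormal radial profile, monomial and
# quadrature frequency responses, windowed spatial kernel design, and the
# monomial / reconstruction banks used by the denoising pipeline.

#' Lognormal radial filter profile
#'
#' Radial amplitude specification shared by all bandpass filters in a bank:
#' `R(rho) = exp(C * ln^2(rho / u0))` with `C = -4 / (B^2 ln 2)`, so that the
#' amplitude is 1 at the centre frequency `u0` and 1/2 at `u0 * 2^(B/2)`,
#' half an octave bandwidth away.
#'
#' @param u0 centre frequency in radians per sample, in (0, pi].
#' @param bandwidth relative bandwidth B in octaves (> 0). The defaults
#'   u0 = 3*pi/5 and B = 2.5 are the values used for the 4D CT application.
#' @return an object of class `radial_spec` with fields `u0`, `bandwidth`
#'   and the derived exponent constant `C_exp`.
#' @export
radial_spec <- function(u0 = 3 * pi / 5, bandwidth = 2.5) {
  if (!is.finite(u0) || u0 <= 0 || u0 > pi) stop("u0 must be in (0, pi]")
  if (!is.finite(bandwidth) || bandwidth <= 0) stop("bandwidth must be > 0")
  structure(
    list(u0 = u0, bandwidth = bandwidth,
         C_exp = -4 / (bandwidth^2 * log(2))),
    class = "radial_spec"
  )
}

#' Evaluate the lognormal radial profile
#'
#' @param rho frequency magnitudes (>= 0); vector or array.
#' @param spec a [radial_spec()].
#' @return amplitudes in \[0, 1\]; exactly 1 at `rho = u0` and 0 at
#'   `rho = 0` (continuous extension of the lognormal).
#' @export
lognormal_radial <- function(rho, spec = radial_spec()) {
  if (any(!is.finite(rho))) stop("non-finite rho")
  if (any(rho < 0)) stop("rho must be >= 0")
  out <- rho
  pos <- rho > 0
  out[!pos] <- 0
  out[pos] <- exp(spec$C_exp * log(rho[pos] / spec$u0)^2)
  out
}

#' Angular frequency grid for an FFT-ordered array
#'
#' Builds the per-axis angular frequencies in (-pi, pi] (DC at index 1,
#' matching the convolution engine's unshifted FFT layout), the radial
#' magnitude field `rho = ||u||` and the unit-direction fields
#' `uhat_a = u_a / rho` (defined 0 at DC).
#'
#' @param extent integer extents per axis (length 1 to 4; padded with
#'   singletons).
#' @return an object of class `frequency_grid` with fields `extent`, `u`
#'   (list of per-axis frequency vectors), `rho` and `uhat`.
#' @export
frequency_grid <- function(extent) {
  extent <- as.integer(extent)
  if (length(extent) < 4L) extent <- c(extent, rep(1L, 4L - length(extent)))
  u <- lapply(extent, function(n) {
    k <- 0:(n - 1L)
    k[k > n / 2] <- k[k > n / 2] - n
    2 * pi * k / n
  })
  rho2 <- array(0, extent)
  for (a in 1:4) {
    if (extent[a] > 1L) rho2 <- rho2 + broadcast_axis(u[[a]], extent, a)^2
  }
  rho <- sqrt(rho2)
  nz <- rho > 0
  uhat <- lapply(1:4, function(a) {
    ua <- broadcast_axis(u[[a]], extent, a)
    out <- array(0, extent)
    out[nz] <- ua[nz] / rho[nz]
    out
  })
  structure(list(extent = extent, u = u, rho = rho, uhat = uhat),
            class = "frequency_grid")
}

# frequency grids are pure functions of the extent; cache them because the
# pipeline requests the same shapes repeatedly.
.grid_cache <- new.env(parent = emptyenv())

frequency_grid_cached <- function(extent) {
  key <- paste(extent, collapse = "x")
  g <- .grid_cache[[key]]
  if (is.null(g)) {
    g <- frequency_grid(extent)
    if (length(ls(.grid_cache)) > 16L) rm(list = ls(.grid_cache), envir = .grid_cache)
    .grid_cache[[key]] <- g
  }
  g
}

#' Ideal monomial frequency response
#'
#' Order-1 responses are `-i R(rho) uhat_m` (odd and imaginary in the
#' frequency domain, hence real odd spatial kernels); order-2 responses are
#' `R(rho) uhat_m uhat_n` (real and even). The DC bin is exactly zero.
#'
#' @param order 1 or 2.
#' @param indices axis index m (order 1) or c(m, n) (order 2), axes numbered
#'   x=1, y=2, z=3, t=4.
#' @param grid a [frequency_grid()].
#' @param spec a [radial_spec()].
#' @return complex (order 1) or real (order 2) array on the grid.
#' @export
monomial_frequency_response <- function(order, indices, grid, spec = radial_spec()) {
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  R <- lognormal_radial(grid$rho, spec)
  if (order == 1L) {
    -1i * R * grid$uhat[[indices[1L]]]
  } else {
    R * grid$uhat[[indices[1L]]] * grid$uhat[[indices[2L]]]
  }
}

#' Ideal quadrature frequency response (reference constructor)
#'
#' `R(rho) (uhat' n)^2` on the half-space `uhat' n > 0` and zero elsewhere:
#' the classical single-sided filter whose response magnitude is phase
#' invariant. Provided as a reference; the pipeline estimates tensors from
#' the monomial bank.
#'
#' @param direction unit direction vector (length up to 4).
#' @param grid a [frequency_grid()].
#' @param spec a [radial_spec()].
#' @return real array on the grid.
#' @export
quadrature_frequency_response <- function(direction, grid, spec = radial_spec()) {
  direction <- c(direction, rep(0, 4L - length(direction)))
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction vector must be nonzero")
  if (abs(nrm - 1) > 1e-8) stop("direction must be a unit vector")
  dotp <- array(0, grid$extent)
  for (a in 1:4) {
    if (direction[a] != 0) dotp <- dotp + direction[a] * grid$uhat[[a]]
  }
  lognormal_radial(grid$rho, spec) * dotp^2 * (dotp > 0)
}

# Reconstruction radial split: lowpass L(rho) = cos^2(rho/2) clipped at
# rho = pi, highpass 1 - L(rho). L + (1 - L) * sum(uhat^2) = 1 identically
# on every non-DC bin, which makes the reconstruction an exact allpass when
# the control tensor is the identity.
reconstruction_lowpass_profile <- function(rho) {
  L <- cos(pmin(rho, pi) / 2)^2
  L
}

reconstruction_response <- function(order, indices, grid) {
  L <- reconstruction_lowpass_profile(grid$rho)
  if (order == 0L) {
    L
  } else {
    (1 - L) * grid$uhat[[indices[1L]]] * grid$uhat[[indices[2L]]]
  }
}

#' Design a windowed spatial kernel from an ideal frequency response
#'
#' Realizes an ideal frequency response as a small real spatial kernel:
#' inverse transform on the design grid, centring, separable raised-cosine
#' windowing over the support, cropping, exact parity symmetrization, and
#' band normalization (bandpass/highpass kernels are made exactly zero-sum,
#' the lowpass kernel unit-sum). The kernel is stored in correlation
#' orientation: correlating a signal with it reproduces the ideal response.
#'
#' @param freq_response complex or real array (the ideal response, DC at
#'   index 1).
#' @param support odd support per axis (scalar recycled over non-singleton
#'   axes of the design grid).
#' @param band one of "bandpass", "highpass", "lowpass", "allpass";
#'   controls sum normalization.
#' @param order,indices,parity metadata stored on the kernel; parity
#'   `NULL` is inferred from the response (imaginary-dominant = odd).
#' @param match_point,match_value optional exact gain calibration: the
#'   kernel is scaled so its transfer function at the angular frequency
#'   vector `match_point` projects onto `match_value` (the ideal response
#'   there). `NULL` matches at the ideal response's peak design-grid bin.
#' @return an object of class `filter_kernel` with fields `values` (4D
#'   array), `order`, `indices`, `parity`, `band`.
#' @export
design_spatial_kernel <- function(freq_response, support,
                                  band = c("bandpass", "highpass", "lowpass", "allpass"),
                                  order = NA_integer_, indices = integer(0),
                                  parity = NULL, match_point = NULL,
                                  match_value = NULL) {
  band <- match.arg(band)
  freq_response <- as_dim4(freq_response)
  ext <- dim(freq_response)
  if (length(support) == 1L) {
    support <- ifelse(ext > 1L, support, 1L)
  }
  support <- as.integer(c(support, rep(1L, 4L - length(support))))
  if (any(support %% 2L == 0L)) stop("support must be odd per axis")
  if (any(support > ext)) stop("support exceeds design grid extent")

  if (is.null(parity)) {
    parity <- if (sum(abs(Im(freq_response))) > sum(abs(Re(freq_response))))
      "odd" else "even"
  }

  h <- Re(stats::fft(freq_response, inverse = TRUE)) / prod(ext)
  # centre the kernel: move the origin (index 1) to floor(n/2)+1
  h <- shift4(h, -(ext %/% 2L))
  ctr <- ext %/% 2L + 1L
  r <- (support - 1L) %/% 2L
  h <- h[(ctr[1L] - r[1L]):(ctr[1L] + r[1L]),
         (ctr[2L] - r[2L]):(ctr[2L] + r[2L]),
         (ctr[3L] - r[3L]):(ctr[3L] + r[3L]),
         (ctr[4L] - r[4L]):(ctr[4L] + r[4L]), drop = FALSE]

  # separable raised-cosine window, 1 at the centre, ->0 just past the edge
  for (a in 1:4) {
    if (support[a] > 1L) {
      off <- seq_len(support[a]) - (r[a] + 1L)
      w <- 0.5 * (1 + cos(pi * off / (r[a] + 1L)))
      h <- h * broadcast_axis(w, dim(h), a)
    }
  }

  # enforce exact parity (point symmetry through the centre)
  h <- if (parity == "odd") (h - reverse_all(h)) / 2 else (h + reverse_all(h)) / 2

  # correlation orientation: correlating with rev(k) equals convolving
  # with k, so store the reversed kernel (a no-op for even parity)
  h <- reverse_all(h)

  # windowing attenuates the realized passband; restore the gain by
  # matching the realized transfer function to the ideal at (or near) the
  # passband peak, so odd and even bank members keep matched amplitudes at
  # the centre frequency (the property behind tensor phase invariance)
  if (is.null(match_point)) {
    Hr <- stats::fft(pad_kernel_for_correlation(h, ext))
    imax <- which.max(Mod(freq_response))
    Hu <- Hr[imax]
    ideal <- freq_response[imax]
  } else {
    Hu <- kernel_transfer_point(h, match_point)
    ideal <- match_value
  }
  if (Mod(Hu) > 0) h <- h * Re(Conj(Hu) * ideal) / Mod(Hu)^2

  if (band %in% c("bandpass", "highpass")) {
    if (parity == "even") h <- h - mean(h)  # odd kernels sum to 0 already
  } else if (band == "lowpass") {
    h <- h / sum(h)
  }

  structure(
    list(values = h, order = as.integer(order), indices = as.integer(indices),
         parity = parity, band = band),
    class = "filter_kernel"
  )
}

# Transfer function of a correlation-oriented kernel at one continuous
# angular frequency: H(u) = sum_off g(off) exp(+i u . off).
kernel_transfer_point <- function(g, u) {
  u <- c(u, rep(0, 4L - length(u)))
  d <- dim(g)
  ph <- array(0, d)
  for (a in 1:4) {
    if (d[a] > 1L) {
      off <- seq_len(d[a]) - ((d[a] - 1L) %/% 2L + 1L)
      ph <- ph + u[a] * broadcast_axis(off, d, a)
    }
  }
  sum(g * exp(1i * ph))
}

# Gain calibration point and ideal value for a bank member: the centre
# frequency along the filter axis (order 1 and diagonal order 2) or along
# the plane diagonal (off-diagonal order 2).
monomial_match <- function(order, indices, spec) {
  u <- rep(0, 4L)
  if (order == 1L || indices[1L] == indices[2L]) {
    u[indices[1L]] <- spec$u0
    val <- if (order == 1L) -1i else 1
  } else {
    u[indices] <- spec$u0 / sqrt(2)
    val <- 0.5
  }
  list(point = u, value = val)
}

highpass_match <- function(indices) {
  u <- rep(0, 4L)
  if (indices[1L] == indices[2L]) {
    u[indices[1L]] <- pi
    val <- 1
  } else {
    u[indices] <- pi / sqrt(2)
    val <- 0.5
  }
  list(point = u, value = val)
}

default_design_grid <- function(dim) c(64L, 48L, 32L)[dim - 1L]

#' Build the monomial filter bank
#'
#' All order-1 and order-2 monomial filters for dimensionality d: d odd
#' first-order filters (x, y, z, t) plus d(d+1)/2 even second-order filters,
#' i.e. 5 filters in 2D, 9 in 3D and 14 in 4D, with a common lognormal
#' radial profile.
#'
#' @param dim dimensionality 2, 3 or 4.
#' @param spec a [radial_spec()]; the defaults are the CT settings.
#' @param support spatial kernel support per (active) axis; default 7.
#' @param design_grid design grid side used for the windowed realization.
#' @return an object of class `filter_bank` (fields `kernels`, `n_f`,
#'   `radial`, `dim`, `support`, `type`).
#' @export
build_monomial_bank <- function(dim, spec = radial_spec(), support = 7L,
                                design_grid = default_design_grid(dim)) {
  if (!dim %in% 2:4) stop("dim must be 2, 3 or 4")
  ext <- c(rep(as.integer(design_grid), dim), rep(1L, 4L - dim))
  grid <- frequency_grid_cached(ext)
  kernels <- list()
  for (m in seq_len(dim)) {
    Fm <- monomial_frequency_response(1L, m, grid, spec)
    mp <- monomial_match(1L, c(m, m), spec)
    kernels[[length(kernels) + 1L]] <-
      design_spatial_kernel(Fm, support, band = "bandpass",
                            order = 1L, indices = m, parity = "odd",
                            match_point = mp$point, match_value = mp$value)
  }
  p <- comp_pairs(dim)
  for (k in seq_len(nrow(p))) {
    Fk <- monomial_frequency_response(2L, p[k, ], grid, spec)
    mp <- monomial_match(2L, p[k, ], spec)
    kernels[[length(kernels) + 1L]] <-
      design_spatial_kernel(Fk, support, band = "bandpass",
                            order = 2L, indices = p[k, ], parity = "even",
                            match_point = mp$point, match_value = mp$value)
  }
  structure(
    list(kernels = kernels, n_f = length(kernels), radial = spec,
         dim = as.integer(dim), support = as.integer(support),
         type = "monomial"),
    class = "filter_bank"
  )
}

#' Build the reconstruction filter bank
#'
#' One zeroth-order isotropic lowpass filter with radial response
#' `L(rho) = cos^2(rho/2)` (clipped at rho = pi) plus d(d+1)/2 directional
#' highpass filters with responses `(1 - L(rho)) uhat_m uhat_n`: 4 filters
#' in 2D, 7 in 3D, 11 in 4D. By construction
#' `L + (1 - L) * sum_m uhat_m^2 = 1` on every non-DC bin, so reconstruction
#' with an identity control tensor is an exact allpass.
#'
#' @param dim dimensionality 2, 3 or 4.
#' @param support spatial kernel support per (active) axis; default 11.
#' @param design_grid design grid side used for the windowed realization.
#' @return an object of class `filter_bank`.
#' @export
build_reconstruction_bank <- function(dim, support = 11L,
                                      design_grid = default_design_grid(dim)) {
  if (!dim %in% 2:4) stop("dim must be 2, 3 or 4")
  ext <- c(rep(as.integer(design_grid), dim), rep(1L, 4L - dim))
  grid <- frequency_grid_cached(ext)
  kernels <- list(
    design_spatial_kernel(reconstruction_response(0L, NULL, grid), support,
                          band = "lowpass", order = 0L, parity = "even")
  )
  p <- comp_pairs(dim)
  for (k in seq_len(nrow(p))) {
    Fk <- reconstruction_response(2L, p[k, ], grid)
    mp <- highpass_match(p[k, ])
    kernels[[length(kernels) + 1L]] <-
      design_spatial_kernel(Fk, support, band = "highpass",
                            order = 2L, indices = p[k, ], parity = "even",
                            match_point = mp$point, match_value = mp$value)
  }
  structure(
    list(kernels = kernels, n_f = length(kernels), radial = NULL,
         dim = as.integer(dim), support = as.integer(support),
         type = "reconstruction"),
    class = "filter_bank"
  )
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("filter_bank: %s, dim %d, %d kernels, support %d\n",
              x$type, x$dim, x$n_f, x$support))
  invisible(x)
}

# Hermitian projection H(k) <- (H(k) + conj(H(-k)))/2. On even-extent grids
# the Nyquist bin is its own mirror and the unit direction there is sign
# ambiguous (+pi and -pi coincide), so odd responses and cross terms
# u_m u_n cannot be realized by a real filter exactly at those bins; the
# projection zeroes them there, which is what the windowed spatial kernels
# do implicitly via the real part.
hermitianize <- function(H) {
  d <- dim(H)
  mi <- lapply(d, function(n) if (n == 1L) 1L else c(1L, rev(seq_len(n)[-1L])))
  (H + Conj(H[mi[[1L]], mi[[2L]], mi[[3L]], mi[[4L]], drop = FALSE])) / 2
}

# Ideal frequency responses of every bank member evaluated on a data grid
# (the FFT backend's exact path).
bank_frequency_responses <- function(bank, extent) {
  extent <- as.integer(extent)
  if (length(extent) < 4L) extent <- c(extent, rep(1L, 4L - length(extent)))
  grid <- frequency_grid_cached(extent)
  lapply(bank$kernels, function(k) {
    H <- if (bank$type == "monomial") {
      monomial_frequency_response(k$order, k$indices, grid, bank$radial)
    } else {
      reconstruction_response(k$order, k$indices, grid)
    }
    hermitianize(as_dim4(H))
  })
}

# bank caching keyed on all design parameters; the pipeline asks for the
# same banks for every slab and every seed
.bank_cache <- new.env(parent = emptyenv())

cached_bank <- function(type, dim, spec = NULL, support) {
  key <- paste(type, dim, support,
               if (is.null(spec)) "" else paste(spec$u0, spec$bandwidth),
               sep = "|")
  b <- .bank_cache[[key]]
  if (is.null(b)) {
    b <- if (type == "monomial") build_monomial_bank(dim, spec, support)
         else build_reconstruction_bank(dim, support)
    .bank_cache[[key]] <- b
  }
  b
}

#' Export a filter bank to disk
#'
#' Writes the kernel arrays as a flat little-endian float64 binary file plus
#' a JSON metadata sidecar (kernel shapes, orders, direction indices, radial
#' spec), so that a bank can be reloaded bit-exactly.
#'
#' @param bank a `filter_bank`.
#' @param path output path for the binary payload; metadata goes to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_filter_bank <- function(bank, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (k in bank$kernels) writeBin(as.vector(k$values), con, size = 8L, endian = "little")
  meta <- list(
    type = bank$type, dim = bank$dim, support = bank$support, n_f = bank$n_f,
    radial = if (!is.null(bank$radial))
      list(u0 = bank$radial$u0, bandwidth = bank$radial$bandwidth),
    kernels = lapply(bank$kernels, function(k)
      list(shape = dim(k$values), order = k$order, indices = k$indices,
           parity = k$parity, band = k$band))
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a filter bank written by [write_filter_bank()]
#'
#' @param path path to the binary payload.
#' @return a `filter_bank`.
#' @export
read_filter_bank <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  kernels <- lapply(seq_len(meta$n_f), function(i) {
    km <- meta$kernels[[i]]
    shp <- as.integer(unlist(km$shape))
    vals <- readBin(con, "double", n = prod(shp), size = 8L, endian = "little")
    structure(
      list(values = array(vals, shp),
           order = as.integer(km$order),
           indices = as.integer(unlist(km$indices)),
           parity = km$parity, band = km$band),
      class = "filter_kernel"
    )
  })
  radial <- if (!is.null(meta$radial) && length(meta$radial))
    radial_spec(meta$radial$u0, meta$radial$bandwidth)
  structure(
    list(kernels = kernels, n_f = meta$n_f, radial = radial,
         dim = as.integer(meta$dim), support = as.integer(meta$support),
         type = meta$type),
    class = "filter_bank"
  )
}
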