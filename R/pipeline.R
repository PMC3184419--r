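# The complete denoising chain: lowpass + downsample, tensor estimation at
# half resolution, magnitude and shape mapping, control-tensor smoothing,
# on-the-fly interpolation back to full resolution, tensor-weighted
# reconstruction, slab-wise execution with exact overlap margins, and the
# multiplication / storage cost calculators.

#' Pipeline configuration
#'
#' @param alpha,beta,sigma M-function parameters (see [mapping_params()]).
#' @param backend `"fft"` (exact ideal frequency responses) or `"spatial"`
#'   (windowed kernels with compact support; required for exact slab
#'   processing).
#' @param slab_size number of output z-slices per slab run, or `NULL` to
#'   process the volume monolithically. The input interval per run is
#'   derived from the exact dependency margin so that slab and monolithic
#'   results agree.
#' @param use_normalized_conv use normalized convolution for the separable
#'   lowpass stages (border handling; with the circular core this matters
#'   only when an explicit certainty is attached).
#' @param u0,bandwidth lognormal radial parameters of the monomial bank.
#' @param support_monomial,support_reconstruction spatial kernel supports
#'   (7 and 11 by default).
#' @param mag_exponent magnitude exponent (8).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.55, beta = 1.5, sigma = 0.1,
                            backend = c("fft", "spatial"), slab_size = NULL,
                            use_normalized_conv = TRUE,
                            u0 = 3 * pi / 5, bandwidth = 2.5,
                            support_monomial = 7L,
                            support_reconstruction = 11L,
                            mag_exponent = 8L) {
  backend <- match.arg(backend)
  structure(
    list(params = mapping_params(alpha, beta, sigma, mag_exponent),
         backend = backend,
         slab_size = if (!is.null(slab_size)) as.integer(slab_size),
         use_normalized_conv = isTRUE(use_normalized_conv),
         radial = radial_spec(u0, bandwidth),
         support_monomial = as.integer(support_monomial),
         support_reconstruction = as.integer(support_reconstruction)),
    class = "pipeline_config"
  )
}

#' Lowpass filter and downsample a volume by 2 in x, y, z
#'
#' Separable \[1, 2, 1\]/4 lowpass on the spatial axes followed by keeping
#' the even-index samples (0, 2, 4, ... zero-based), giving `ceiling(n/2)`
#' samples per spatial axis; the time axis is untouched. With a certainty
#' attached the lowpass uses normalized convolution.
#'
#' @param vol a [volume4d()].
#' @param cert optional certainty array for normalized convolution.
#' @param modes per-axis boundary mode (default all-circular core).
#' @return the downsampled `volume4d`.
#' @export
downsample2_xyz <- function(vol, cert = NULL, modes = "circular") {
  vol <- as_volume4d(vol)
  ext <- dim(vol$values)
  b3 <- c(1, 2, 1) / 4
  kern <- lapply(1:4, function(a) if (a == 4L || ext[a] == 1L) NULL else b3)
  lp <- if (is.null(cert)) {
    separable_conv(vol, kern, modes)
  } else {
    normalized_conv(vol, cert, kern, modes)
  }
  keep <- lapply(1:4, function(a) {
    if (a == 4L) seq_len(ext[a]) else seq(1L, ext[a], by = 2L)
  })
  out <- lp$values[keep[[1L]], keep[[2L]], keep[[3L]], keep[[4L]], drop = FALSE]
  volume4d(out, spacing = vol$spacing * c(2, 2, 2, 1),
           periodic_t = vol$periodic_t)
}

# Linear interpolation weights for upsampling a half-resolution axis of
# extent m to a full-resolution axis of extent n = 2m or 2m - 1. Sample p
# (zero-based) sits at half-resolution coordinate p/2; even-extent axes
# wrap circularly (consistent with the circular core), odd-extent axes end
# exactly on the last source sample.
upsample_axis_index <- function(n, m) {
  p <- 0:(n - 1L)
  coord <- p / 2
  i0 <- floor(coord)
  w <- coord - i0
  i1 <- (i0 + 1L) %% m
  list(i0 = as.integer(i0) + 1L, i1 = as.integer(i1) + 1L, w = w)
}

#' Interpolate a control tensor field to full resolution
#'
#' Multilinear interpolation of every component over x, y, z (no temporal
#' interpolation); values at source sample positions are reproduced
#' exactly.
#'
#' @param ctf a `control_tensor_field` at half resolution.
#' @param target_extent full-resolution extent (spatial extents 2m or
#'   2m - 1 per axis; equal t extent).
#' @return a `control_tensor_field` on the target grid.
#' @export
interpolate_control_tensor <- function(ctf, target_extent) {
  target_extent <- as.integer(target_extent)
  if (length(target_extent) < 4L) {
    target_extent <- c(target_extent, rep(1L, 4L - length(target_extent)))
  }
  src <- ctf$extent
  if (target_extent[4L] != src[4L]) stop("t extents must match")
  for (a in 1:3) {
    if (!target_extent[a] %in% c(2L * src[a], 2L * src[a] - 1L, src[a])) {
      stop("target extent on axis ", a, " is not a factor-2 refinement")
    }
  }
  interp_one <- function(x) {
    for (a in 1:3) {
      n <- target_extent[a]; m <- dim(x)[a]
      if (n == m) next
      ix <- upsample_axis_index(n, m)
      A0 <- index_axis(x, a, ix$i0)
      A1 <- index_axis(x, a, ix$i1)
      wf <- broadcast_axis(ix$w, dim(A0), a)
      x <- A0 * (1 - wf) + A1 * wf
    }
    x
  }
  comps <- lapply(ctf$components, interp_one)
  structure(
    list(components = comps, gamma = if (!is.null(ctf$gamma)) interp_one(ctf$gamma),
         dim = ctf$dim, extent = target_extent,
         valid = lapply(target_extent, function(n) c(1L, n))),
    class = "control_tensor_field"
  )
}

#' Tensor-controlled reconstruction
#'
#' `i_d = i_lp + sum_k w_k C_k i_hp(k)` where `i_lp` is the isotropic
#' lowpass response, `i_hp(k)` the directional highpass responses and `C_k`
#' the control tensor components; diagonal components carry weight 1 and
#' off-diagonal components weight 2 so the directional response equals
#' `uhat' C uhat`. With `C = I` everywhere the reconstruction is an exact
#' allpass (FFT backend).
#'
#' @param vol the full-resolution input [volume4d()].
#' @param ctf a `control_tensor_field`, either at the volume's resolution or
#'   at half resolution (interpolated on the fly).
#' @param bank a reconstruction `filter_bank`.
#' @param backend `"fft"` or `"spatial"`.
#' @return the reconstructed `volume4d`.
#' @export
reconstruct <- function(vol, ctf, bank, backend = c("fft", "spatial")) {
  backend <- match.arg(backend)
  vol <- as_volume4d(vol)
  ext <- dim(vol$values)
  if (bank$type != "reconstruction") stop("bank must be a reconstruction bank")
  if (!identical(as.integer(ctf$extent), ext)) {
    ctf <- interpolate_control_tensor(ctf, ext)
  }
  H <- backend_responses(bank, ext, backend)
  resp <- apply_responses_fft(vol$values, H)
  p <- comp_pairs(bank$dim)
  if (length(ctf$components) != nrow(p)) {
    stop("control tensor has ", length(ctf$components),
         " components but the bank expects ", nrow(p))
  }
  out <- resp[[1L]]
  for (c in seq_len(nrow(p))) {
    w <- if (p[c, 1L] == p[c, 2L]) 1 else 2
    out <- out + w * ctf$components[[c]] * resp[[c + 1L]]
  }
  volume4d(out, spacing = vol$spacing, periodic_t = vol$periodic_t)
}

# Exact dependency margin of the full chain in full-resolution z-slices:
# reconstruction support 11 -> +/-5; interpolation needs half slices
# ceil(z/2) +/- (monomial 3 + tensor lowpass 2 + control lowpass 2) = 7,
# each half slice needing full-resolution 2h +/- 1 from the pre-downsample
# lowpass: 2*(ceil(z/2) + 7) + 1 <= z + 16.
slab_margin_full <- function(cfg) {
  rm_rec <- (cfg$support_reconstruction - 1L) %/% 2L
  half <- (cfg$support_monomial - 1L) %/% 2L + 2L + 2L
  max(rm_rec, 2L * half + 2L)
}

# One monolithic pass over (a slab of) the data. Returns the denoised
# values and the smoothed-tensor magnitude field (for the two-pass global
# normalization).
denoise_core <- function(values, cfg, d, gamma_max = NULL, tmag_only = FALSE) {
  vol <- volume4d(values)
  mono <- cached_bank("monomial", d, cfg$radial, cfg$support_monomial)
  ds <- downsample2_xyz(vol)
  resp <- apply_monomial_bank(ds, mono, cfg$backend)
  tf <- assemble_tensor(resp)
  tf <- smooth_tensor(tf)
  mag <- tensor_magnitude(tf, cfg$params$mag_exponent, norm_max = gamma_max)
  if (tmag_only) return(list(t_mag = mag$t_mag))
  ctf <- control_tensor(tf, mag, cfg$params)
  ctf <- smooth_tensor(ctf)
  rec_bank <- cached_bank("reconstruction", d, NULL, cfg$support_reconstruction)
  out <- reconstruct(vol, ctf, rec_bank, cfg$backend)
  list(values = out$values, t_mag = mag$t_mag)
}

#' Denoise a 4D volume
#'
#' Runs the complete adaptive-filtering chain: spatial lowpass + downsample
#' by 2, monomial filtering and structure-tensor assembly at half
#' resolution, tensor smoothing, magnitude mapping (M-function) and
#' eigenvalue-free shape mapping, control-tensor smoothing, interpolation
#' back to full resolution, and tensor-weighted reconstruction. Volumes
#' with trailing singleton extents are processed with banks of the matching
#' dimensionality (2D and 3D restrictions of the same algorithm).
#'
#' With `cfg$slab_size` set, the z-axis is processed in slabs: the output
#' range is partitioned, each run ingests the exact dependency margin on
#' both sides (wrapping circularly at the dataset ends), and the magnitude
#' normalization maximum is computed in a first pass over all slabs so that
#' slab and monolithic results agree to rounding.
#'
#' @param vol a [volume4d()] or array.
#' @param cfg a [pipeline_config()].
#' @return the denoised `volume4d`.
#' @export
denoise_4d <- function(vol, cfg = pipeline_config()) {
  vol <- as_volume4d(vol)
  ext <- dim(vol$values)
  d <- infer_dim(ext)
  if (any(ext[1:2] < 8L)) stop("x and y extents must be at least 8 (downsample stage)")

  nz <- ext[3L]
  if (is.null(cfg$slab_size) || cfg$slab_size >= nz || nz == 1L) {
    res <- denoise_core(vol$values, cfg, d)
    return(volume4d(res$values, spacing = vol$spacing, periodic_t = vol$periodic_t))
  }

  margin <- slab_margin_full(cfg)
  starts <- seq(1L, nz, by = cfg$slab_size)
  slabs <- lapply(starts, function(s) {
    o <- c(s, min(s + cfg$slab_size - 1L, nz))      # output z-interval
    in0 <- o[1L] - 1L - margin                      # zero-based input start
    if (in0 %% 2L != 0L) in0 <- in0 - 1L            # keep half-res alignment
    in1 <- o[2L] - 1L + margin
    list(out = o, in0 = in0, in1 = in1)
  })

  # pass 1: dataset-global maximum of the smoothed-tensor magnitude, each
  # slab contributing its assigned half-resolution slices
  gmax <- 0
  for (sl in slabs) {
    zi <- ((sl$in0:sl$in1) %% nz) + 1L
    sub <- vol$values[, , zi, , drop = FALSE]
    tm <- denoise_core(sub, cfg, d, tmag_only = TRUE)$t_mag
    h0 <- ceiling((sl$out[1L] - 1L) / 2)            # first assigned half slice
    h1 <- floor((sl$out[2L] - 1L) / 2)
    hl <- (2L * (h0:h1) - sl$in0) / 2L + 1L         # slab-local half indices
    gmax <- max(gmax, tm[, , hl, , drop = FALSE])
  }

  # pass 2: denoise each slab under the global normalization and crop
  out <- array(0, ext)
  for (sl in slabs) {
    zi <- ((sl$in0:sl$in1) %% nz) + 1L
    sub <- vol$values[, , zi, , drop = FALSE]
    res <- denoise_core(sub, cfg, d, gamma_max = gmax)
    loc <- (sl$out[1L]:sl$out[2L]) - 1L - sl$in0 + 1L
    out[, , sl$out[1L]:sl$out[2L], ] <- res$values[, , loc, , drop = FALSE]
  }
  volume4d(out, spacing = vol$spacing, periodic_t = vol$periodic_t)
}

#' Plan slab runs over the z-axis
#'
#' Operational slab accounting: each run ingests `slab_size` full-resolution
#' slices and yields the valid output slices given by [plan_valid_slices()]
#' (39 for the standard 51-slice spatial-filtering run). Output intervals
#' are disjoint and cover all requested slices; input intervals are clamped
#' to the data extent.
#'
#' @param n_slices total z-slices in the dataset.
#' @param slab_size input slices per run (default 51).
#' @param use_normalized_conv passed to [plan_valid_slices()].
#' @return a data.frame with one row per run: `run`, `out_start`, `out_end`,
#'   `in_start`, `in_end` (1-based inclusive).
#' @export
plan_slabs <- function(n_slices, slab_size = 51L, use_normalized_conv = TRUE) {
  n_slices <- as.integer(n_slices)
  slab_size <- as.integer(slab_size)
  per_run <- plan_valid_slices(slab_size, use_normalized_conv)$final_output
  if (per_run < 1L) stop("slab_size too small: no valid output slices per run")
  n_runs <- as.integer(ceiling(n_slices / per_run))
  margin <- (slab_size - per_run) %/% 2L
  out_start <- (seq_len(n_runs) - 1L) * per_run + 1L
  out_end <- pmin(out_start + per_run - 1L, n_slices)
  in_start <- pmax(out_start - margin, 1L)
  in_end <- pmin(out_end + margin, n_slices)
  data.frame(run = seq_len(n_runs), out_start = out_start, out_end = out_end,
             in_start = in_start, in_end = in_end)
}

#' Multiplication count of direct spatial filtering
#'
#' `n_filters * prod(kernel extents) * prod(data extents)`: one multiply
#' per filter coefficient per output sample. For the 512 x 512 x 445 x 20
#' dataset with 11 reconstruction filters of 11^4 coefficients this is
#' about 3.76e14 ("375 000 billion") multiplications.
#'
#' @param data_extent data extents (any length).
#' @param n_filters number of filters.
#' @param kernel_extent kernel extents (scalar is recycled to the data
#'   dimensionality).
#' @return the multiplication count (double).
#' @export
count_multiplications <- function(data_extent, n_filters, kernel_extent) {
  if (any(data_extent < 1L) || n_filters < 1L || any(kernel_extent < 1L)) {
    stop("extents and filter count must be positive")
  }
  if (length(kernel_extent) == 1L) {
    kernel_extent <- rep(kernel_extent, length(data_extent))
  }
  as.numeric(n_filters) * prod(as.numeric(kernel_extent)) * prod(as.numeric(data_extent))
}

#' Storage requirement of a set of filter responses
#'
#' `prod(data extents) * n_responses * bytes_per_value` bytes (decimal GB =
#' 1e9 bytes): about 103 GB for the 11 reconstruction filter responses of
#' the 4D CT dataset in single precision.
#'
#' @param data_extent data extents (any length).
#' @param n_responses number of response fields kept.
#' @param bytes_per_value bytes per stored value (4 for float32).
#' @return the byte count (double).
#' @export
storage_bytes <- function(data_extent, n_responses, bytes_per_value = 4) {
  if (any(data_extent < 1L) || n_responses < 1L || bytes_per_value <= 0) {
    stop("extents, response count and bytes per value must be positive")
  }
  prod(as.numeric(data_extent)) * as.numeric(n_responses) * as.numeric(bytes_per_value)
}
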