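# Internal helpers shared across modules. Everything operates on plain 4D
# arrays ordered (x, y, z, t) with x varying fastest; lower-dimensional data
# is carried with trailing singleton extents.

axis_names4 <- c("x", "y", "z", "t")

# Coerce scalar/vector/matrix/3D input to a 4D array without copying values.
as_dim4 <- function(x) {
  if (is.null(dim(x))) dim(x) <- c(length(x), 1L, 1L, 1L)
  d <- dim(x)
  if (length(d) > 4L) stop("arrays with more than 4 dimensions are not supported")
  if (length(d) < 4L) dim(x) <- c(d, rep(1L, 4L - length(d)))
  x
}

# Effective dimensionality: index of the last non-singleton axis (>= 2).
# Active axes must be leading, e.g. (nx, ny, 1, 1) is a 2D problem.
infer_dim <- function(extent) {
  nz <- which(extent > 1L)
  if (length(nz) == 0L) return(2L)
  max(2L, max(nz))
}

# Upper-triangle (row-major) index pairs (m, n), m <= n, of a symmetric d x d
# tensor. For d = 4 this is the t1..t10 layout xx, xy, xz, xt, yy, yz, yt,
# zz, zt, tt.
comp_pairs <- function(d) {
  out <- matrix(0L, nrow = d * (d + 1L) / 2L, ncol = 2L)
  k <- 0L
  for (m in seq_len(d)) for (n in m:d) {
    k <- k + 1L
    out[k, ] <- c(m, n)
  }
  out
}

comp_names <- function(d) {
  p <- comp_pairs(d)
  paste0(axis_names4[p[, 1L]], axis_names4[p[, 2L]])
}

# d x d matrix giving the component index of entry (i, j).
comp_lookup <- function(d) {
  p <- comp_pairs(d)
  L <- matrix(0L, d, d)
  for (k in seq_len(nrow(p))) {
    L[p[k, 1L], p[k, 2L]] <- k
    L[p[k, 2L], p[k, 1L]] <- k
  }
  L
}

# Circular shift read: out[i] = a[(i - 1 + off) mod n + 1] along one axis.
shift_axis <- function(a, axis, off) {
  n <- dim(a)[axis]
  idx <- ((seq_len(n) - 1L + off) %% n) + 1L
  index_axis(a, axis, idx)
}

# Arbitrary re-indexing along one axis, keeping dimensions.
index_axis <- function(a, axis, idx) {
  switch(axis,
    a[idx, , , , drop = FALSE],
    a[, idx, , , drop = FALSE],
    a[, , idx, , drop = FALSE],
    a[, , , idx, drop = FALSE]
  )
}

# Simultaneous circular shift along all four axes.
shift4 <- function(a, off) {
  d <- dim(a)
  ii <- lapply(1:4, function(k) ((seq_len(d[k]) - 1L + off[k]) %% d[k]) + 1L)
  a[ii[[1L]], ii[[2L]], ii[[3L]], ii[[4L]], drop = FALSE]
}

# Point reflection through the centre sample (parity operator for kernels
# with odd extents): k(-x) for x measured from the centre.
reverse_all <- function(a) {
  d <- dim(a)
  a[rev(seq_len(d[1L])), rev(seq_len(d[2L])), rev(seq_len(d[3L])), rev(seq_len(d[4L])),
    drop = FALSE]
}

# Inverse DFT normalized, real part (inputs are Hermitian by construction).
ifft_real <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# Broadcast a per-axis vector to the full array shape.
broadcast_axis <- function(v, extent, axis) {
  a <- array(0, extent)
  array(v[slice.index(a, axis)], extent)
}

stopifnot_finite <- function(x, what = "values") {
  if (!all(is.finite(x))) stop(sprintf("non-finite %s encountered", what))
  invisible(TRUE)
}
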