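# Independent brute-force oracles. These deliberately use different
# algorithms (scalar loops, explicit matrix products) from the package's
# vectorized / FFT implementations.

# circular correlation by explicit scalar loops over output voxels and taps
oracle_circular_correlation <- function(a, k) {
  da <- dim(a)
  dk <- dim(k)
  r <- (dk - 1L) %/% 2L
  out <- array(0, da)
  for (x in seq_len(da[1])) for (y in seq_len(da[2])) {
    for (z in seq_len(da[3])) for (t in seq_len(da[4])) {
      acc <- 0
      for (i in seq_len(dk[1])) for (j in seq_len(dk[2])) {
        for (l in seq_len(dk[3])) for (m in seq_len(dk[4])) {
          xx <- ((x - 1 + i - 1 - r[1]) %% da[1]) + 1
          yy <- ((y - 1 + j - 1 - r[2]) %% da[2]) + 1
          zz <- ((z - 1 + l - 1 - r[3]) %% da[3]) + 1
          tt <- ((t - 1 + m - 1 - r[4]) %% da[4]) + 1
          acc <- acc + k[i, j, l, m] * a[xx, yy, zz, tt]
        }
      }
      out[x, y, z, t] <- acc
    }
  }
  out
}

# circular correlation by tap accumulation over wrapped index tables;
# independent of both the scalar oracle and the package's FFT path
oracle_shift_correlation <- function(a, k) {
  da <- dim(a)
  dk <- dim(k)
  r <- (dk - 1L) %/% 2L
  out <- array(0, da)
  for (i in seq_len(dk[1])) for (j in seq_len(dk[2])) {
    for (l in seq_len(dk[3])) for (m in seq_len(dk[4])) {
      kv <- k[i, j, l, m]
      if (kv == 0) next
      ix <- ((seq_len(da[1]) - 1 + i - 1 - r[1]) %% da[1]) + 1
      iy <- ((seq_len(da[2]) - 1 + j - 1 - r[2]) %% da[2]) + 1
      iz <- ((seq_len(da[3]) - 1 + l - 1 - r[3]) %% da[3]) + 1
      it <- ((seq_len(da[4]) - 1 + m - 1 - r[4]) %% da[4]) + 1
      out <- out + kv * a[ix, iy, iz, it, drop = FALSE]
    }
  }
  out
}

# upper-triangle row-major component pairs of a symmetric d x d matrix
oracle_pairs <- function(d) {
  p <- NULL
  for (m in seq_len(d)) for (n in m:d) p <- rbind(p, c(m, n))
  p
}

# structure tensor at one voxel by explicit Q1 Q1' + Q2 Q2' matrix products
oracle_tensor_voxel <- function(fr, d) {
  p <- oracle_pairs(d)
  q1 <- matrix(fr[seq_len(d)], ncol = 1)
  Q2 <- matrix(0, d, d)
  for (c in seq_len(nrow(p))) {
    Q2[p[c, 1], p[c, 2]] <- fr[d + c]
    Q2[p[c, 2], p[c, 1]] <- fr[d + c]
  }
  q1 %*% t(q1) + Q2 %*% Q2
}

# random symmetric matrix with prescribed eigenvalues
random_symmetric <- function(d, lambda) {
  Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  Q %*% diag(lambda, d) %*% t(Q)
}

# pack a symmetric matrix into the row-major upper-triangle component order
sym_to_components <- function(S) {
  d <- nrow(S)
  p <- oracle_pairs(d)
  S[p]
}

components_to_sym <- function(v, d) {
  p <- oracle_pairs(d)
  S <- matrix(0, d, d)
  for (c in seq_len(nrow(p))) {
    S[p[c, 1], p[c, 2]] <- v[c]
    S[p[c, 2], p[c, 1]] <- v[c]
  }
  S
}

random_volume <- function(extent, seed = 1) {
  set.seed(seed)
  volume4d(array(stats::rnorm(prod(extent)), extent))
}

# identity control tensor field on a grid
identity_control_field <- function(extent, d = 4L) {
  p <- oracle_pairs(d)
  comps <- lapply(seq_len(nrow(p)), function(c) {
    array(as.numeric(p[c, 1] == p[c, 2]), extent)
  })
  nm <- c("xx", "xy", "xz", "xt", "yy", "yz", "yt", "zz", "zt", "tt")
  if (d == 2) nm <- c("xx", "xy", "yy")
  if (d == 3) nm <- c("xx", "xy", "xz", "yy", "yz", "zz")
  names(comps) <- nm
  structure(list(components = comps, dim = d, extent = extent,
                 valid = lapply(extent, function(n) c(1L, n))),
            class = "control_tensor_field")
}

withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("d4d")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
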