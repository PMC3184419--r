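# Magnitude and shape mapping: M/mu closed forms, magnitude bounds, the
# eigenvalue-free matrix polynomial against the eigendecomposition oracle,
# and the classical 2D reference mapping.

test_that("M-function closed-form values and domain checks", {
  p <- mapping_params(alpha = 0.55, beta = 1.5, sigma = 0.1)
  expect_equal(m_function(0, p), 0)
  expect_equal(m_function(1, p), 1 / (1 + 0.1^1.5), tolerance = 1e-12)
  expect_equal(m_function(1, mapping_params(sigma = 0)), 1)
  # overshoot: an interior maximum above 1 for the CT parameters
  g <- seq(0.001, 1, by = 0.001)
  mg <- m_function(g, p)
  expect_gt(max(mg), 1)
  expect_gt(which.max(mg), 1)
  expect_lt(which.max(mg), length(g))
  # monotone near zero (soft threshold, no oscillation)
  expect_true(all(diff(mg[g < 0.2]) > 0))
  expect_error(m_function(1.5, p), "gamma0")
  expect_error(m_function(-0.1, p), "gamma0")
})

test_that("mu-function fixed points, midpoint and monotonicity", {
  expect_equal(mu_function(0, 0.55, 1.5), 0)
  expect_equal(mu_function(1, 0.55, 1.5), 1)
  for (a in c(0.2, 0.5, 0.55, 0.8)) {
    for (b in c(1, 1.5, 3)) expect_equal(mu_function(a, a, b), 0.5)
  }
  # spec spot value: lambda = (1, 0.3), alpha = 0.5, beta = 2
  expect_equal(mu_function(0.3, 0.5, 2), 0.15^2 / (0.15^2 + 0.35^2),
               tolerance = 1e-12)
  x <- seq(0, 1, by = 0.001)
  expect_true(all(diff(mu_function(x, 0.55, 1.5)) >= 0))
  expect_error(mu_function(0.5, 1.2, 1), "alpha")
  expect_error(mu_function(2, 0.5, 1), "phi0")
})

test_that("tensor magnitude matches closed forms and brackets lambda1", {
  mk_tf <- function(S) {
    d <- nrow(S)
    comps <- as.list(sym_to_components(S))
    names(comps) <- if (d == 4) c("xx", "xy", "xz", "xt", "yy", "yz", "yt",
                                  "zz", "zt", "tt") else c("xx", "xy", "yy")
    comps <- lapply(comps, function(v) array(v, c(1, 1, 1, 1)))
    structure(list(components = comps, dim = d, extent = c(1L, 1L, 1L, 1L),
                   valid = list(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L))),
              class = "tensor_field4d")
  }
  expect_equal(as.vector(tensor_magnitude(mk_tf(diag(c(1, 0, 0, 0))))$t_mag), 1)
  expect_equal(as.vector(tensor_magnitude(mk_tf(diag(1, 4)))$t_mag), 4^(1 / 16),
               tolerance = 1e-12)
  expect_equal(as.vector(tensor_magnitude(mk_tf(diag(c(2, 1, 0, 0))))$t_mag),
               65537^(1 / 16), tolerance = 1e-12)
  # bounds lambda1 <= T_mag <= 4^(1/16) lambda1 on random PSD tensors
  set.seed(40)
  for (i in 1:50) {
    lam <- sort(runif(4), decreasing = TRUE)
    tm <- as.vector(tensor_magnitude(mk_tf(random_symmetric(4, lam)))$t_mag)
    expect_gte(tm, lam[1] - 1e-10)
    expect_lte(tm, 4^(1 / 16) * lam[1] + 1e-10)
  }
  # all-zero field: gamma0 defined as 0, no division error
  z <- tensor_magnitude(mk_tf(diag(0, 4)))
  expect_equal(as.vector(z$gamma0), 0)
  expect_error(tensor_magnitude(mk_tf(diag(1, 4)), exponent = 6), "power of 2")
})

test_that("scalar eigenvalue transfer has the documented shape", {
  expect_equal(eigen_transfer(0), 0)
  expect_equal(eigen_transfer(1), 1)
  expect_equal(eigen_transfer(0.5), 0.98046875)
  x <- seq(0, 1, by = 0.0005)
  fx <- eigen_transfer(x)
  expect_true(all(diff(fx) >= -1e-12))
  expect_true(all(fx >= -1e-12 & fx <= 1 + 1e-12))
  # S-shape: small eigenvalues shrink, large ones grow
  expect_lt(eigen_transfer(0.1), 0.1)
  expect_gt(eigen_transfer(0.45), 0.45)
})

test_that("matrix-polynomial shape mapping equals the eigendecomposition oracle", {
  set.seed(41)
  n <- 1000
  That <- matrix(0, n, 10)
  lams <- matrix(runif(4 * n), n, 4)
  Qs <- vector("list", n)
  for (i in 1:n) {
    Q <- qr.Q(qr(matrix(rnorm(16), 4)))
    Qs[[i]] <- Q
    That[i, ] <- sym_to_components(Q %*% diag(lams[i, ]) %*% t(Q))
  }
  C <- map_tensor_shape(That, 4)
  worst <- 0
  for (i in 1:n) {
    want <- Qs[[i]] %*% diag(eigen_transfer(lams[i, ])) %*% t(Qs[[i]])
    worst <- max(worst, max(abs(C[i, ] - sym_to_components(want))))
  }
  expect_lt(worst, 1e-10)
})

test_that("control tensor handles fixed points, scaling and zero magnitude", {
  mk_tf <- function(S, scale = 1) {
    comps <- as.list(sym_to_components(S) * scale)
    names(comps) <- c("xx", "xy", "xz", "xt", "yy", "yz", "yt", "zz", "zt", "tt")
    comps <- lapply(comps, function(v) array(v, c(1, 1, 1, 1)))
    structure(list(components = comps, dim = 4L, extent = c(1L, 1L, 1L, 1L),
                   valid = list(c(1L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L))),
              class = "tensor_field4d")
  }
  p <- mapping_params()

  # zero tensor -> zero control tensor
  tf0 <- mk_tf(diag(0, 4))
  ct0 <- control_tensor(tf0, tensor_magnitude(tf0), p)
  expect_true(all(vapply(ct0$components, function(c) all(c == 0), TRUE)))

  # That = 0.5 I: scalar chain gives shape 0.98046875 I
  That <- matrix(sym_to_components(diag(0.5, 4)), 1)
  shape <- map_tensor_shape(That, 4)
  expect_equal(as.vector(shape),
               sym_to_components(diag(0.98046875, 4)), tolerance = 1e-12)

  # scaling the tensor changes only gamma, not the shape
  set.seed(42)
  S <- random_symmetric(4, c(1, 0.6, 0.3, 0.1))
  tfa <- mk_tf(S); tfb <- mk_tf(S, scale = 5)
  maga <- tensor_magnitude(tfa); magb <- tensor_magnitude(tfb)
  cta <- control_tensor(tfa, maga, p); ctb <- control_tensor(tfb, magb, p)
  # same gamma0 (both normalized by their own max) -> identical C
  expect_equal(vapply(cta$components, as.vector, 0),
               vapply(ctb$components, as.vector, 0), tolerance = 1e-10)

  # rank-one normalized tensor is a fixed point of the shape transfer
  v <- c(1, 0, 0, 0)
  tfr <- mk_tf(tcrossprod(v))
  ctr <- control_tensor(tfr, tensor_magnitude(tfr), p)
  gshape <- vapply(ctr$components, as.vector, 0) / m_function(1, p)
  expect_equal(gshape, sym_to_components(tcrossprod(v)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("2D eigen-based mapping matches its closed forms", {
  p <- mapping_params(alpha = 0.5, beta = 2, sigma = 0.1)
  # isotropic tensor: C = gamma I
  C <- control_tensor_2d(diag(0.5, 2), p, gamma0 = 0.5 * sqrt(2))
  gam <- m_function(0.5 * sqrt(2), p)
  expect_equal(C, gam * diag(1, 2), tolerance = 1e-12)
  # rank-1 tensor: C = gamma e1 e1'
  v <- c(1, 2) / sqrt(5)
  C <- control_tensor_2d(0.8 * tcrossprod(v), p)
  expect_equal(C, m_function(0.8, p) * tcrossprod(v), tolerance = 1e-12)
  # lambda = (1, 0.3) not normalized -> error; normalized via gamma0 arg
  T <- diag(c(1, 0.3))
  expect_error(control_tensor_2d(T, p), "normalize")
  C <- control_tensor_2d(T, p, gamma0 = 1)
  phi <- 0.15^2 / (0.15^2 + 0.35^2)
  expect_equal(diag(C), m_function(1, p) * c(1, phi), tolerance = 1e-12)
  expect_equal(control_tensor_2d(diag(0, 2), p), matrix(0, 2, 2))
})
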