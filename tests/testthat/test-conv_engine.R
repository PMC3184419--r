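# Convolution engine: separable / nonseparable / FFT paths against
# brute-force oracles, normalized convolution, and valid-slice accounting.

test_that("separable convolution: identity, unit-sum and oracle agreement", {
  v <- random_volume(c(8, 8, 8, 4), seed = 1)
  idk <- list(1, 1, 1, 1)
  expect_equal(separable_conv(v, idk, "circular")$values, v$values)

  cv <- volume4d(array(3.7, c(6, 6, 6, 3)))
  sm <- separable_conv(cv, list(c(1, 2, 1) / 4, c(1, 2, 1) / 4, NULL, NULL), "circular")
  expect_equal(sm$values, cv$values, tolerance = 1e-12)

  # outer-product kernel: separable path vs direct 4D correlation oracle
  k1 <- c(0.25, 0.5, 0.25); k2 <- c(-1, 0, 1); k3 <- c(1, 3, 1) / 5; k4 <- c(2, 5, 2) / 9
  k4d <- outer(outer(outer(k1, k2), k3), k4)
  dim(k4d) <- c(3, 3, 3, 3)
  sep <- separable_conv(v, list(k1, k2, k3, k4), "circular")
  orc <- oracle_shift_correlation(v$values, k4d)
  expect_equal(max(abs(sep$values - orc)), 0, tolerance = 1e-10)

  # valid-mode bookkeeping
  val <- separable_conv(v, list(c(1, 1, 1) / 3, NULL, c(1, 2, 1) / 4, NULL), "valid")
  expect_equal(val$valid[[1]], c(2L, 7L))
  expect_equal(val$valid[[3]], c(2L, 7L))
  expect_equal(val$valid[[2]], c(1L, 8L))
  expect_error(separable_conv(v, list(rep(1, 9) / 9, NULL, NULL, NULL), "valid"),
               "longer")
})

test_that("nonseparable correlation matches impulse algebra and the scalar oracle", {
  v <- random_volume(c(6, 6, 6, 4), seed = 2)
  delta <- array(0, c(3, 3, 3, 3)); delta[2, 2, 2, 2] <- 1
  expect_equal(nonseparable_conv(v, delta, "circular")$values, v$values)

  # correlating an impulse with k copies the reversed kernel at the impulse
  imp <- array(0, c(7, 7, 7, 5)); imp[4, 4, 4, 3] <- 1
  set.seed(3)
  k <- array(rnorm(3^4), c(3, 3, 3, 3))
  out <- nonseparable_conv(volume4d(imp), k, "circular")$values
  expect_equal(out[3:5, 3:5, 3:5, 2:4], k[3:1, 3:1, 3:1, 3:1], tolerance = 1e-12)

  # scalar quadruple-loop oracle on a tiny volume
  v6 <- random_volume(c(6, 6, 4, 3), seed = 4)
  set.seed(5)
  k2 <- array(rnorm(3 * 3 * 3 * 3), c(3, 3, 3, 3))
  expect_equal(nonseparable_conv(v6, k2, "circular")$values,
               oracle_circular_correlation(v6$values, k2), tolerance = 1e-9)

  # valid bookkeeping shrinks by the half-width
  out <- nonseparable_conv(v6, k2, "valid")
  expect_equal(out$valid[[1]], c(2L, 5L))
})

test_that("convolution is linear", {
  v1 <- random_volume(c(6, 6, 4, 3), seed = 6)
  v2 <- random_volume(c(6, 6, 4, 3), seed = 7)
  set.seed(8)
  k <- array(rnorm(81), c(3, 3, 3, 3))
  lhs <- nonseparable_conv(volume4d(2 * v1$values - 3 * v2$values), k, "circular")$values
  rhs <- 2 * nonseparable_conv(v1, k, "circular")$values -
         3 * nonseparable_conv(v2, k, "circular")$values
  expect_equal(max(abs(lhs - rhs)), 0, tolerance = 1e-9)
})

test_that("FFT path equals direct circular correlation", {
  # allpass response returns the input
  v <- random_volume(c(8, 8, 8, 4), seed = 9)
  expect_equal(fft_filter(v, array(1 + 0i, dim(v$values)))$values, v$values,
               tolerance = 1e-12)

  # spatial-kernel path vs the tap-shift circular oracle, including a
  # kernel longer than the time axis (circular fold)
  for (kd in list(c(3, 3, 3, 3), c(5, 5, 5, 5))) {
    set.seed(sum(kd))
    k <- array(rnorm(prod(kd)), kd)
    got <- fft_filter(v, k)$values
    want <- oracle_shift_correlation(v$values, k)
    expect_equal(max(abs(got - want)), 0, tolerance = 1e-9)
  }
  expect_error(fft_filter(v, array(1 + 0i, c(4, 4, 4, 4)), type = "response"),
               "mismatch")
})

test_that("two even kernels pack into one complex transform", {
  v <- random_volume(c(8, 8, 6, 4), seed = 10)
  g <- frequency_grid(dim(v$values))
  sp <- radial_spec()
  H1 <- denoise4d:::hermitianize(as.array(
    monomial_frequency_response(2L, c(1L, 1L), g, sp)))
  H2 <- denoise4d:::hermitianize(as.array(
    monomial_frequency_response(2L, c(2L, 2L), g, sp)))
  packed <- denoise4d:::apply_responses_fft(v$values, list(H1, H2))
  r1 <- fft_filter(v, H1)$values
  r2 <- fft_filter(v, H2)$values
  expect_equal(max(abs(packed[[1]] - r1)), 0, tolerance = 1e-9)
  expect_equal(max(abs(packed[[2]] - r2)), 0, tolerance = 1e-9)
})

test_that("normalized convolution renormalizes lost certainty", {
  # full certainty reduces to plain convolution
  v <- random_volume(c(8, 8, 6, 4), seed = 11)
  kern <- list(c(1, 2, 1) / 4, c(1, 2, 1) / 4, NULL, NULL)
  cert1 <- array(1, dim(v$values))
  nc <- normalized_conv(v, cert1, kern, "circular")
  pc <- separable_conv(v, kern, "circular")
  expect_equal(nc$values, pc$values, tolerance = 1e-12)
  expect_true(all(nc$defined))

  # constants are preserved under arbitrary positive-support certainty
  cv <- volume4d(array(4.2, c(8, 8, 1, 1)))
  set.seed(12)
  cert <- array(stats::runif(64) > 0.4, c(8, 8, 1, 1)) * 1
  ncc <- normalized_conv(cv, cert, list(c(1, 1, 1) / 3, c(1, 1, 1) / 3, NULL, NULL),
                         "circular")
  expect_equal(ncc$values[ncc$defined], rep(4.2, sum(ncc$defined)), tolerance = 1e-12)

  # 1D toy: s = [5,7,9], c = [1,1,0], f = [1,1,1] -> centre (5+7)/2 = 6
  s <- volume4d(array(c(5, 7, 9), c(3, 1, 1, 1)))
  c1 <- array(c(1, 1, 0), c(3, 1, 1, 1))
  out <- normalized_conv(s, c1, list(c(1, 1, 1), NULL, NULL, NULL), "valid")
  expect_equal(out$values[2, 1, 1, 1], 6)

  # all-zero certainty: all-invalid output, not an exception
  z <- normalized_conv(s, c1 * 0, list(c(1, 1, 1), NULL, NULL, NULL), "circular")
  expect_false(any(z$defined))
  expect_error(normalized_conv(s, c1, list(c(1, -1, 1), NULL, NULL, NULL)),
               "nonnegative")
})

test_that("valid-slice accounting reproduces the printed chain counts", {
  # standard convolution, 34 slices: 32 -> 16 -> 10 -> 6 -> 2
  p <- plan_valid_slices(34, use_normalized_conv = FALSE)
  expect_equal(p$after_lowpass, 32L)
  expect_equal(p$after_downsample, 16L)
  expect_equal(p$after_monomial, 10L)
  expect_equal(p$after_tensor_lowpass, 6L)
  expect_equal(p$after_control_lowpass, 2L)

  # normalized convolution, 51 slices: 26 half-res, 20 valid, 39 out
  p <- plan_valid_slices(51, use_normalized_conv = TRUE)
  expect_equal(p$after_downsample, 26L)
  expect_equal(p$after_monomial, 20L)
  expect_equal(p$after_control_lowpass, 20L)
  expect_equal(p$final_output, 39L)

  # FFT-chunk size from the paper's second configuration: 31 -> 16 -> 10
  p <- plan_valid_slices(31, use_normalized_conv = TRUE)
  expect_equal(p$after_downsample, 16L)
  expect_equal(p$after_monomial, 10L)

  # everything consumed
  expect_equal(plan_valid_slices(7, use_normalized_conv = FALSE)$final_output, 0L)
  expect_error(plan_valid_slices(0))
})
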