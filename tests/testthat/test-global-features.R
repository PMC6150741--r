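test_that("four equally occupied bins give the hand-computed histogram values", {
  q <- make_qv(array(1:4, c(4, 1, 1)), G = 4)
  h <- histogram_features(q)
  expect_equal(h$hist_mean, 2.5)
  expect_equal(h$hist_median, 2.5)
  expect_equal(h$hist_entropy, 2.0)
  expect_equal(h$hist_energy, 0.25)
})

test_that("constant volume: entropy 0, energy 1, sd 0, moment flags set", {
  q <- make_qv(array(1L, c(3, 3, 2)), G = 8)
  h <- histogram_features(q)
  expect_equal(h$hist_entropy, 0)
  expect_equal(h$hist_energy, 1)
  expect_equal(h$hist_sd, 0)
  expect_equal(h$hist_skewness, 0)
  expect_true(all(c("hist_skewness", "hist_kurtosis") %in% attr(h, "flags")))
})

test_that("symmetric histograms have zero skewness", {
  q <- make_qv(array(c(1L, 2L, 2L, 3L, 1L, 3L), c(6, 1, 1)), G = 3)
  expect_equal(histogram_features(q)$hist_skewness, 0, tolerance = 1e-12)
})

test_that("histogram features are invariant to voxel permutation", {
  set.seed(51)
  bins <- array(sample.int(8, 60, replace = TRUE), c(5, 4, 3))
  q1 <- make_qv(bins, G = 8)
  perm <- array(sample(as.integer(bins)), dim(bins))
  q2 <- make_qv(perm, G = 8)
  expect_equal(unclass(histogram_features(q1)),
               unclass(histogram_features(q2)))
})

test_that("entropy is maximal and energy minimal exactly at uniformity", {
  unif <- make_qv(array(rep(1:4, 3), c(12, 1, 1)), G = 4)
  skew <- make_qv(array(c(rep(1L, 9), 2L, 3L, 4L), c(12, 1, 1)), G = 4)
  hu <- histogram_features(unif); hs <- histogram_features(skew)
  expect_equal(hu$hist_entropy, log2(4))
  expect_gt(hu$hist_entropy, hs$hist_entropy)
  expect_lt(hu$hist_energy, hs$hist_energy)
})

test_that("box-counting dimension of a filled constant square is 2", {
  q <- make_qv(array(5L, c(64, 64, 1)), G = 32)
  fd <- boxcount_fd(q)
  expect_equal(fd$fractal_fd_mean, 2.0, tolerance = 0.05)
})

test_that("box-counting dimension of a constant straight line is 1", {
  bins <- array(NA_integer_, c(64, 64, 1))
  mask <- array(FALSE, c(64, 64, 1))
  bins[32, , 1] <- 5L
  mask[32, , 1] <- TRUE
  fd <- boxcount_fd(make_qv(bins, mask, G = 32))
  expect_equal(fd$fractal_fd_mean, 1.0, tolerance = 0.1)
})

test_that("identical slices give zero FD spread; shifts leave FD unchanged", {
  set.seed(52)
  sl <- matrix(sample.int(16, 32 * 32, replace = TRUE), 32, 32)
  bins <- array(rep(sl, 3), c(32, 32, 3))
  fd <- boxcount_fd(make_qv(bins, G = 16))
  expect_equal(fd$fractal_fd_sd, 0)
  # constant gray-level shift of the quantized surface
  fd2 <- boxcount_fd(make_qv(bins + 4L, G = 20))
  expect_equal(fd2$fractal_fd_mean, fd$fractal_fd_mean, tolerance = 0.05)
})

test_that("lacunarity is exactly 1 for a constant image and larger for a gappy one", {
  expect_equal(lacunarity(make_qv(array(3L, c(16, 16, 1)), G = 4)), 1)
  bins <- array(1L, c(16, 16, 1))
  bins[8, 8, 1] <- 32L  # one bright voxel in a flat background
  expect_gt(lacunarity(make_qv(bins, G = 32), box_sizes = 2L), 1)
})

test_that("checkerboard lacunarity matches exhaustive gliding-box enumeration", {
  bins <- array(1L, c(8, 8, 1))
  bins[, , 1] <- outer(1:8, 1:8, function(i, j) 1L + (i + j) %% 2L)
  q <- make_qv(bins, G = 2)
  # brute force: every 2x2 window position
  masses <- c()
  for (i in 1:7) for (j in 1:7) masses <- c(masses, sum(bins[i:(i + 1), j:(j + 1), 1]))
  lam_bf <- 1 + mean((masses - mean(masses))^2) / mean(masses)^2
  expect_equal(lacunarity(q, box_sizes = 2L), lam_bf, tolerance = 1e-12)
  # translation invariance of the periodic pattern
  shifted <- make_qv(array(3L - bins, dim(bins)), G = 2)
  expect_equal(lacunarity(shifted, box_sizes = 2L), lam_bf, tolerance = 1e-12)
})

test_that("R/S Hurst of white noise is near 0.5 at profile length 256", {
  set.seed(53)
  bins <- array(sample.int(32, 256 * 8, replace = TRUE), c(256, 8, 1))
  h <- hurst_exponent(make_qv(bins, G = 32))
  expect_equal(as.numeric(h), 0.5, tolerance = 0.1)
})

test_that("a linear ramp profile is strongly persistent (H near 1)", {
  bins <- array(rep(1:32, each = 8), c(256, 4, 1))
  h <- hurst_exponent(make_qv(bins, G = 32))
  expect_gt(as.numeric(h), 0.8)
})

test_that("smoother fields have larger Hurst exponents", {
  rough <- generate_phantom(small_spec(seed = 54, correlation_length = 0.5))
  smooth <- generate_phantom(small_spec(seed = 54, correlation_length = 5))
  hr <- hurst_exponent(preprocess_study(rough$volume, rough$mask))
  hs <- hurst_exponent(preprocess_study(smooth$volume, smooth$mask))
  expect_gt(as.numeric(hs), as.numeric(hr))
})
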