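test_that("constant volume NGTDM: zero contrast, coarseness at cap", {
  q <- make_qv(array(4L, c(4, 4, 2)), G = 8)
  f <- ngtdm_features(compute_ngtdm(q))
  expect_equal(f$ngtdm_contrast, 0)
  expect_equal(f$ngtdm_coarseness, 1e12)
  expect_equal(f$ngtdm_busyness, 0)
  expect_true("ngtdm_busyness" %in% attr(f, "flags"))
})

test_that("4x4 two-level pattern matches the exhaustive NGTDM oracle", {
  bins <- array(c(1L, 2L, 1L, 2L,
                  2L, 1L, 2L, 1L,
                  1L, 1L, 2L, 2L,
                  2L, 2L, 1L, 1L), c(4, 4, 1))
  q <- make_qv(bins, G = 2)
  m <- compute_ngtdm(q)
  bf <- bf_ngtdm(q)
  expect_equal(m$levels, bf$levels)
  expect_equal(m$n_valid, bf$n_valid)
  expect_equal(m$s, bf$s, tolerance = 1e-12)
  expect_equal(m$p, bf$p, tolerance = 1e-12)
  f <- ngtdm_features(m)
  fb <- bf_ngtdm_features(bf)
  expect_equal(unclass(f)[names(fb)], fb, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("a checkerboard is busier than a half-and-half split", {
  ck <- outer(1:8, 1:8, function(i, j) 1L + (i + j) %% 2L)
  hh <- matrix(rep(c(1L, 2L), each = 32), 8, 8)
  f_ck <- ngtdm_features(compute_ngtdm(make_qv(array(ck, c(8, 8, 1)), G = 2)))
  f_hh <- ngtdm_features(compute_ngtdm(make_qv(array(hh, c(8, 8, 1)), G = 2)))
  expect_gt(f_ck$ngtdm_contrast, f_hh$ngtdm_contrast)
})

test_that("run matrix of a single row matches hand enumeration", {
  bins <- array(c(1L, 1L, 2L, 2L, 2L), c(1, 1, 5))
  q <- make_qv(bins, G = 2)
  m <- compute_glrlm(q, directions = list(c(0L, 0L, 1L)))
  expect_equal(m$r[1, 2], 1)  # level 1, length 2
  expect_equal(m$r[2, 3], 1)  # level 2, length 3
  expect_equal(m$Nr, 2)
  f <- glrlm_features(m)
  expect_equal(f$glrl_sre, (1 / 4 + 1 / 9) / 2, tolerance = 1e-12)
  expect_equal(f$glrl_intensity_variability, 1)
  expect_equal(f$glrl_run_length_variability, 1)
  expect_equal(f$glrl_run_percentage, 2 / 5)
})

test_that("constant row: single-run closed forms", {
  L <- 7L
  q <- make_qv(array(3L, c(1, 1, L)), G = 4)
  f <- glrlm_features(compute_glrlm(q, directions = list(c(0L, 0L, 1L))))
  expect_equal(f$glrl_sre, 1 / L^2)
  expect_equal(f$glrl_lre, L^2)
  expect_equal(f$glrl_run_percentage, 1 / L)
})

test_that("finer quantization drives run percentage toward 1", {
  set.seed(71)
  x <- array(runif(10 * 10 * 4), c(10, 10, 4))
  m <- roi_mask(array(TRUE, c(10, 10, 4)))
  rp <- vapply(c(2L, 8L, 32L), function(G) {
    q <- quantize(image_volume(x), m, G = G)
    glrlm_features(compute_glrlm(q))$glrl_run_percentage
  }, numeric(1))
  expect_true(all(diff(rp) > 0))
})

test_that("2x2 zone example matches hand enumeration", {
  bins <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  q <- make_qv(bins, G = 2)
  z <- compute_glzsm(q)
  expect_identical(z$Nz, 2L)
  f <- glzsm_features(z)
  expect_equal(f$glzsm_short_zone_emphasis, (1 / 9 + 1) / 2, tolerance = 1e-12)
  expect_equal(f$glzsm_intensity_nonuniformity, 1)
  expect_equal(f$glzsm_size_zone_variability, 1)
  expect_equal(f$glzsm_zone_percentage, 0.5)
})

test_that("constant volume: single-zone closed forms", {
  q <- make_qv(array(2L, c(3, 3, 2)), G = 4)
  Np <- 18
  f <- glzsm_features(compute_glzsm(q))
  expect_equal(f$glzsm_zone_percentage, 1 / Np)
  expect_equal(f$glzsm_large_zone_emphasis, Np^2)
})

test_that("checkerboard under 6-connectivity is all singleton zones", {
  ck <- outer(1:6, 1:6, function(i, j) 1L + (i + j) %% 2L)
  q <- make_qv(array(ck, c(6, 6, 1)), G = 2)
  f <- glzsm_features(compute_glzsm(q, connectivity = "6"))
  expect_equal(f$glzsm_short_zone_emphasis, 1)
  expect_equal(f$glzsm_zone_percentage, 1)
})

test_that("mass conservation holds for runs and zones on random volumes", {
  set.seed(72)
  for (rep in 1:5) {
    q <- random_qv(c(6, 5, 3), G = 3)
    Np <- sum(q$mask)
    r <- compute_glrlm(q)
    expect_equal(sum(r$r %*% seq_len(ncol(r$r))), Np * 13)
    z <- compute_glzsm(q)
    expect_equal(sum(z$zones$count * z$zones$size), Np)
  }
})

test_that("features are invariant to translation inside a larger grid", {
  set.seed(73)
  q <- random_qv(c(5, 5, 2), G = 3, p_mask = 1)
  big_bins <- array(1L, c(9, 9, 4))
  big_mask <- array(FALSE, c(9, 9, 4))
  big_bins[3:7, 2:6, 2:3] <- q$data
  big_mask[3:7, 2:6, 2:3] <- TRUE
  q2 <- make_qv(big_bins, big_mask, G = 3)
  expect_equal(unclass(ngtdm_features(compute_ngtdm(q))),
               unclass(ngtdm_features(compute_ngtdm(q2))), tolerance = 1e-12)
  expect_equal(glrlm_features(compute_glrlm(q)),
               glrlm_features(compute_glrlm(q2)), tolerance = 1e-12)
  expect_equal(glzsm_features(compute_glzsm(q)),
               glzsm_features(compute_glzsm(q2)), tolerance = 1e-12)
})

test_that("matrices match the brute-force oracles exactly on random volumes", {
  set.seed(74)
  for (rep in 1:10) {
    q <- random_qv(c(5, 5, 3), G = 3)
    # runs: integer equality of every cell
    r <- compute_glrlm(q)
    expect_identical(unname(r$r[, seq_len(ncol(bf_glrlm(q)))]),
                     unname(bf_glrlm(q)))
    # zones: identical multiset of (level, size)
    z <- zones_to_matrix(compute_glzsm(q))
    bz <- bf_glzsm(q)
    bz <- bz[order(bz[, "level"], bz[, "size"]), , drop = FALSE]
    expect_identical(unname(apply(z, 2, as.integer)), unname(bz))
  }
})

test_that("coarser textures have longer runs and larger zones", {
  lre <- lze <- matrix(NA_real_, 20, 2)
  for (s in 1:20) {
    for (ci in 1:2) {
      cl <- c(0.8, 4)[ci]
      ph <- generate_phantom(small_spec(seed = 100 + s, correlation_length = cl))
      q <- preprocess_study(ph$volume, ph$mask)
      lre[s, ci] <- glrlm_features(compute_glrlm(q))$glrl_lre
      lze[s, ci] <- glzsm_features(compute_glzsm(q))$glzsm_large_zone_emphasis
    }
  }
  expect_gt(median(lre[, 2]), median(lre[, 1]))
  expect_gt(median(lze[, 2]), median(lze[, 1]))
})
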