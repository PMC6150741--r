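test_that("hand-computed toy set reproduces wCV, r and limits of agreement", {
  x1 <- c(10, 20); x2 <- c(12, 18)
  w <- wcv(x1, x2)
  expect_equal(as.numeric(w), 100 * sqrt(2) / 15, tolerance = 1e-12)
  expect_equal(signif(as.numeric(w), 4), 9.428)
  expect_equal(repeatability_coefficient(x1, x2), 3.92)
  ba <- bland_altman(x1, x2)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$loa_upper, 1.96 * sd(c(-2, 2)), tolerance = 1e-12)
  expect_equal(signif(ba$loa_upper, 4), 5.544)
  expect_equal(ba$loa_lower, -ba$loa_upper)
})

test_that("identical replicates give all-zero repeatability statistics", {
  x <- c(3, 8, 1, 9)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$loa_lower, 0)
  expect_equal(ba$loa_upper, 0)
  expect_equal(as.numeric(wcv(x, x)), 0)
  expect_equal(repeatability_coefficient(x, x), 0)
})

test_that("Bland-Altman estimates are translation-equivariant", {
  set.seed(81)
  x1 <- rnorm(12, 50, 5); x2 <- rnorm(12, 50, 5)
  ba <- bland_altman(x1, x2)
  ba_c <- bland_altman(x1 + 3.7, x2)
  expect_equal(ba_c$mean_difference, ba$mean_difference + 3.7)
  expect_equal(ba_c$loa_lower, ba$loa_lower + 3.7)
  expect_equal(ba_c$loa_upper, ba$loa_upper + 3.7)
})

test_that("wCV is scale-invariant and r obeys the s_w identity", {
  set.seed(82)
  x1 <- runif(20, 10, 30); x2 <- x1 * (1 + rnorm(20, 0, 0.1))
  expect_equal(as.numeric(wcv(3 * x1, 3 * x2)), as.numeric(wcv(x1, x2)),
               tolerance = 1e-12)
  d <- x1 - x2
  s_w <- sqrt(sum(d^2) / (2 * length(d)))
  expect_equal(repeatability_coefficient(x1, x2), 1.96 * sqrt(2) * s_w,
               tolerance = 1e-12)
})

test_that("subject order permutation leaves every statistic unchanged", {
  set.seed(83)
  x1 <- runif(15, 5, 9); x2 <- x1 + rnorm(15, 0, 0.3)
  p <- sample(15)
  expect_equal(bland_altman(x1[p], x2[p]), bland_altman(x1, x2))
  expect_equal(as.numeric(wcv(x1[p], x2[p])), as.numeric(wcv(x1, x2)))
  expect_equal(repeatability_coefficient(x1[p], x2[p]),
               repeatability_coefficient(x1, x2))
})

test_that("reliability bands map wCV values to the declared classes", {
  expect_identical(classify_reliability(c(0, 9.43, 10)),
                   c("good", "good", "good"))
  expect_identical(classify_reliability(c(10.1, 12, 15)),
                   c("acceptable", "acceptable", "acceptable"))
  expect_identical(classify_reliability(c(15.1, 29.9)),
                   c("intermediate", "intermediate"))
  expect_identical(classify_reliability(c(30, 49.9)),
                   c("moderate-poor", "moderate-poor"))
  expect_identical(classify_reliability(c(50, 120)),
                   c("unreliable", "unreliable"))
  expect_error(classify_reliability(-1), "non-negative")
})

test_that("sign-mixed or zero-mean features are flagged uninterpretable", {
  w <- wcv(c(-2, 5, 3), c(-1, 4, 3.5))
  expect_false(attr(w, "interpretable"))
  w2 <- wcv(c(-1, 1), c(1, -1))
  expect_false(attr(w2, "interpretable"))
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("wCV recovers the true multiplicative CV on synthetic pairs", {
  set.seed(84)
  for (n in c(50, 200)) {
    cv <- 0.10
    reps <- vapply(1:40, function(i) {
      truth <- runif(n, 80, 120)
      x1 <- truth * (1 + rnorm(n, 0, cv))
      x2 <- truth * (1 + rnorm(n, 0, cv))
      as.numeric(wcv(x1, x2))
    }, numeric(1))
    se <- sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - 100 * cv), 3 * se + 0.15)
  }
})

test_that("r covers 95% of absolute differences for Gaussian error", {
  set.seed(85)
  n <- 1e5
  sigma <- 2.5
  d <- rnorm(n, 0, sigma)
  r <- repeatability_coefficient(d, rep(0, n))
  expect_equal(unname(quantile(abs(d), 0.95)) / r, 1, tolerance = 0.02)
})

test_that("repeatability_table validates pairing and orders by registry", {
  feats <- expand.grid(subject_id = c("A", "B", "C"), day = 1:2,
                       feature_name = c("hist_mean", "glcm_entropy"),
                       stringsAsFactors = FALSE)
  set.seed(86)
  feats$value <- runif(nrow(feats), 10, 12)
  tab <- repeatability_table(feats)
  expect_identical(tab$feature_name, c("hist_mean", "glcm_entropy"))
  expect_true(all(c("mean_difference", "loa_lower", "loa_upper",
                    "wcv_percent", "repeatability_coefficient",
                    "reliability_class") %in% names(tab)))
  broken <- feats[-1, ]
  expect_error(repeatability_table(broken), "day-1")
})
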