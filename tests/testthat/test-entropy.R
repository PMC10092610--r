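test_that("coarse-graining implements block means with truncation", {
  expect_equal(coarse_grain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))
  x <- rnorm(100)
  expect_identical(coarse_grain(x, 1), x)
  expect_error(coarse_grain(x, 0), "positive integer")
  expect_error(coarse_grain(rnorm(3), 5), "shorter")
})

test_that("coarse-graining composes across compatible scales", {
  set.seed(14)
  x <- rnorm(120)   # 120 divisible by 2*3, 4*5, 6*2
  for (ab in list(c(2, 3), c(4, 5), c(6, 2))) {
    expect_equal(coarse_grain(coarse_grain(x, ab[1]), ab[2]),
                 coarse_grain(x, ab[1] * ab[2]))
  }
})

test_that("sample entropy handles constant and alternating series", {
  se <- sample_entropy(rep(3.7, 50), m = 2, r = 0.1)
  expect_true(se$defined)
  expect_equal(se$value, 0)
  expect_equal(se$A, se$B)

  x <- rep(c(1, -1), 30)
  se2 <- sample_entropy(x, m = 2, r = 0.2 * sd(x))
  expect_equal(se2$value, 0)   # every m-match extends to m+1

  expect_error(sample_entropy(rnorm(3), m = 2, r = 0.2), "too short")
  expect_error(sample_entropy(rnorm(50), m = 2, r = 0), "r must be > 0")
})

test_that("optimized counts equal the brute-force reference exactly", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    x <- rnorm(n)
    m <- sample(1:3, 1)
    r <- runif(1, 0.1, 0.3) * sd(x)
    fast <- sample_entropy(x, m, r)
    ref <- sample_entropy_naive(x, m, r)
    expect_identical(c(A = fast$A, B = fast$B), ref)
  }
})

test_that("sample entropy is invariant under affine rescaling with r ~ SD", {
  set.seed(12)
  x <- rnorm(300)
  r_frac <- 0.2
  a <- sample_entropy(x, 2, r_frac * sd(x))
  y <- 5 * x + 11
  b <- sample_entropy(y, 2, r_frac * sd(y))
  expect_identical(a$A, b$A)
  expect_identical(a$B, b$B)
})

test_that("white-noise entropy is stable across seeds at N = 1000", {
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    x <- rnorm(1000)
    sample_entropy(x, 2, 0.2 * sd(x))$value
  }, 1)
  # theory for Gaussian white noise, m = 2, r = 0.2 SD: about 2.2 nats
  expect_lt(abs(mean(vals) - 2.2), 0.15)
  expect_lt(sd(vals), 0.15)
})

test_that("mse_curve flags degenerate epochs and short scales", {
  z <- mse_curve(rep(0, 500), "gamma", 1000, scales = 1:5)
  expect_true(all(!z$defined))
  expect_true(all(is.na(z$values)))

  set.seed(3)
  ok <- mse_curve(rnorm(500), "gamma", 1000, scales = c(1, 2, 4))
  expect_true(all(ok$defined))
  expect_true(all(ok$values > 0))
  # a scale leaving fewer than m+2 samples is flagged, not an error
  tiny <- mse_curve(rnorm(500), "gamma", 1000, scales = c(1, 200))
  expect_false(tiny$defined[2])
})

test_that("classic noise ordering: white decreases with scale, 1/f stays flat", {
  set.seed(2024)
  n_epochs <- 20
  scales <- c(1, 2, 4, 6, 8, 10, 12)
  curves <- function(gen) {
    rowMeans(vapply(seq_len(n_epochs), function(i) {
      x <- gen(1000)
      vapply(scales, function(tau) {
        sample_entropy(coarse_grain(x, tau), 2, 0.15 * sd(x))$value
      }, 1)
    }, numeric(length(scales))), na.rm = TRUE)
  }
  white <- curves(function(n) rnorm(n))
  pink <- curves(function(n) pink_noise(n))
  expect_gt(white[1], pink[1])                 # white more irregular at scale 1
  expect_true(all(diff(white) < 0))            # white decays with scale
  expect_gt(pink[length(pink)], white[length(white)])  # crossover at high scale
})

test_that("mse_compare pairs trials and flags zero-variance contrasts", {
  set.seed(6)
  a <- matrix(rnorm(40, mean = 2), nrow = 10, ncol = 4)
  cmp0 <- mse_compare(a, a)
  expect_true(cmp0$mean_test$degenerate)

  b <- a + 0.3
  cmp1 <- mse_compare(b, a)
  expect_true(cmp1$mean_test$degenerate)   # constant per-trial offset

  b2 <- a + matrix(rnorm(40, 0.5, 0.1), 10, 4)
  cmp2 <- mse_compare(b2, a)
  expect_equal(cmp2$mean_test$df, 9)
  expect_gt(cmp2$mean_test$statistic, 0)
  expect_lt(cmp2$mean_test$p_value, 0.05)
  expect_equal(nrow(cmp2$per_scale), 4)
})
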