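test_that("paired t reproduces the textbook statistic and flags degeneracy", {
  res <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$statistic, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)

  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)

  # equals the one-sample t on the differences
  set.seed(10)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(paired_t(a, b)$statistic,
               unname(t.test(a - b)$statistic), tolerance = 1e-12)
})

test_that("wilcoxon signed-rank: exact small-sample p and zero handling", {
  # all five differences positive: two-sided exact p = 2/32
  res <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(0, 0, 0, 0, 0))
  expect_equal(res$p_value, 1 / 16)
  expect_equal(res$statistic, 15)

  tied <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(tied$degenerate)
  expect_equal(tied$n_zero_dropped, 5)

  partial <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5), c(1, 2, 0, 0, 0))
  expect_equal(partial$n_zero_dropped, 2)
})

test_that("one-way ANOVA: F equals t^2 for two groups, degenerate flagged", {
  set.seed(20)
  g1 <- rnorm(12); g2 <- rnorm(12, 0.5)
  res <- one_way_anova(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(res$test$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$test$p_value, tt$p.value, tolerance = 1e-10)

  degen <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_true(degen$test$degenerate)

  three <- one_way_anova(list(a = rnorm(8), b = rnorm(8), c = rnorm(8)))
  expect_equal(nrow(three$posthoc), 3)
  expect_true(all(three$posthoc$adjusted_p >= three$posthoc$p_value))
})

test_that("two-way ANOVA decomposes sums of squares on balanced layouts", {
  set.seed(30)
  n <- 10
  time <- rep(c("baseline", "late"), each = 2 * n)
  cond <- rep(rep(c("saline", "ketamine"), each = n), 2)
  y <- rnorm(4 * n) + (time == "late") * 1 + (cond == "ketamine") * 0.5
  res <- two_way_anova(y, time, cond)
  total_ss <- sum((y - mean(y))^2)
  expect_equal(sum(res$sum_sq), total_ss, tolerance = 1e-9 * total_ss)
  expect_equal(res$term, c("time", "condition", "time:condition", "residual"))

  # additive cell means, no noise: interaction SS is zero
  cells <- c(outer(c(0, 1), c(0, 0.5), "+"))
  y0 <- rep(cells, each = n)
  t0 <- rep(rep(c("b", "l"), each = n), 2)
  c0 <- rep(c("s", "k"), each = 2 * n)
  res0 <- two_way_anova(y0, t0, c0)
  expect_lt(res0$sum_sq[res0$term == "time:condition"], 1e-20)

  expect_error(two_way_anova(y[-1], time[-1][-1], cond[-2]), "balanced|length")
})

test_that("holm-sidak follows the step-down formula with monotonicity", {
  expect_equal(holm_sidak(0.03), 0.03)
  expect_equal(holm_sidak(c(0.01, 0.04)), c(1 - 0.99^2, 0.04))
  # unsorted input keeps its order
  expect_equal(holm_sidak(c(0.04, 0.01)), c(0.04, 1 - 0.99^2))
  set.seed(40)
  p <- runif(20)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p & adj <= 1))
  # permutation equivariance
  perm <- sample(20)
  expect_equal(holm_sidak(p[perm]), adj[perm])
  # monotonicity enforced even when the raw formula would invert
  adj2 <- holm_sidak(c(0.01, 0.011, 0.5))
  expect_true(all(diff(adj2[order(c(0.01, 0.011, 0.5))]) >= 0))
})

test_that("type-I error is near nominal for the whole battery", {
  # moderate simulation sizes; the acceptance suite runs the full-size
  # calibration
  set.seed(50)
  n_sim <- 2000
  alpha <- 0.05
  ci <- function(rate) abs(rate - alpha) < 3 * sqrt(alpha * 0.95 / n_sim)

  rej_t <- mean(replicate(n_sim, paired_t(rnorm(15), rnorm(15))$p_value) < alpha)
  expect_true(ci(rej_t))

  rej_w <- mean(replicate(n_sim,
    wilcoxon_signed_rank(rnorm(12), rnorm(12))$p_value) < alpha)
  expect_lt(rej_w, alpha + 3 * sqrt(alpha * 0.95 / n_sim))  # exact test: conservative ok

  rej_f <- mean(replicate(n_sim,
    one_way_anova(list(rnorm(10), rnorm(10), rnorm(10)))$test$p_value) < alpha)
  expect_true(ci(rej_f))
})
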