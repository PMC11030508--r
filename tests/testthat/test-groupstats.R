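test_that("Welch t-test matches hand evaluation of the Welch formulas", {
  x <- c(2.1, 2.5, 2.3); y <- c(3.0, 3.4, 3.1)
  gc <- welch_t_test(x, y)
  or <- oracle_welch(x, y)
  expect_equal(gc$statistic, or$statistic, tolerance = 1e-10)
  expect_equal(gc$df, or$df, tolerance = 1e-10)
  expect_equal(gc$p_two_tailed, or$p, tolerance = 1e-8)
  # identical samples: t = 0, p = 1
  gc0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gc0$statistic, 0)
  expect_equal(gc0$p_two_tailed, 1)
  # antisymmetry under swapping
  gs <- welch_t_test(y, x)
  expect_equal(gs$statistic, -gc$statistic)
  expect_equal(gs$p_two_tailed, gc$p_two_tailed)
})

test_that("degenerate zero-variance inputs are flagged", {
  eq <- welch_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(eq$p_two_tailed, 1)
  ne <- welch_t_test(c(2, 2, 2), c(3, 3))
  expect_equal(ne$p_two_tailed, 0)
  expect_false(is.na(ne$flag))
  expect_error(welch_t_test(1, c(1, 2)), "n >= 2")
  expect_error(variance_f_test(c(1, 2), c(3, 3)), "zero variance")
})

test_that("variance F-test matches the incomplete-beta and binomial-sum oracles", {
  # the F(0.16; 6, 10) case: CDF = I_x(3, 5), x = 0.96/10.96
  x <- 6 * 0.16 / (6 * 0.16 + 10)
  cdf_binom <- binom_sum_ibeta(x, 3, 5)
  expect_equal(cdf_binom, 0.0179, tolerance = 1e-2 / 1.79)
  p_oracle <- 2 * min(cdf_binom, 1 - cdf_binom)
  expect_equal(p_oracle, 0.0358, tolerance = 1e-3 / 0.0358)
  # implementation on samples engineered to that F with those df
  set.seed(1)
  a <- rnorm(7); a <- (a - mean(a)) / sd(a) * 0.4
  b <- rnorm(11); b <- (b - mean(b)) / sd(b)
  gc <- variance_f_test(a, b)
  expect_equal(gc$statistic, 0.16, tolerance = 1e-10)
  expect_equal(gc$df, c(6, 10))
  expect_equal(gc$p_two_tailed, p_oracle, tolerance = 1e-3)
  # s1^2 = 1, s2^2 = 4, n = 11 each: F = 0.25, df (10, 10)
  a2 <- rnorm(11); a2 <- (a2 - mean(a2)) / sd(a2)
  b2 <- rnorm(11); b2 <- (b2 - mean(b2)) / sd(b2) * 2
  gc2 <- variance_f_test(a2, b2)
  expect_equal(gc2$statistic, 0.25, tolerance = 1e-12)
  x2 <- 10 * 0.25 / (10 * 0.25 + 10)
  expect_equal(gc2$p_two_tailed, 2 * min(ibeta_reg(x2, 5, 5), 1 - ibeta_reg(x2, 5, 5)),
               tolerance = 1e-8)
  # equal samples: F = 1, p = 1
  gc3 <- variance_f_test(a2, a2)
  expect_equal(gc3$statistic, 1)
  expect_equal(gc3$p_two_tailed, 1)
})

test_that("both tests agree with the incomplete-beta oracle across a grid", {
  set.seed(42)
  worst_f <- worst_t <- 0
  for (i in 1:50) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 2)); y <- rnorm(n2, sd = runif(1, 0.5, 2))
    gf <- variance_f_test(x, y)
    worst_f <- max(worst_f, abs(gf$p_two_tailed -
                                  oracle_f_p(gf$statistic, n1 - 1, n2 - 1)))
    gw <- welch_t_test(x, y)
    worst_t <- max(worst_t, abs(gw$p_two_tailed - oracle_welch(x, y)$p))
  }
  expect_lt(worst_f, 1e-8)
  expect_lt(worst_t, 1e-8)
})

test_that("longitudinal comparison aggregates, tests and skips sparse weeks", {
  set.seed(5)
  mk <- function(g, o, w, mu) data.frame(group = g, organoid = o, week = w,
                                         image = 1, tile = 1:5,
                                         feat = rnorm(5, mu, 0.1))
  ft <- rbind(mk("control", "C1", 1, 0), mk("control", "C2", 1, 0),
              mk("control", "C3", 1, 0),
              mk("experimental", "E1", 1, 0), mk("experimental", "E2", 1, 0),
              mk("experimental", "E3", 1, 0),
              mk("control", "C1", 2, 0), mk("control", "C2", 2, 0),
              mk("control", "C3", 2, 0),
              mk("experimental", "E1", 2, 2), mk("experimental", "E2", 2, 2),
              mk("experimental", "E3", 2, 2),
              mk("control", "C1", 3, 0))   # week 3 lacks experimental
  class(ft) <- c("feature_table", "data.frame")
  lc <- longitudinal_compare(ft, features = "feat", switch_week = 1)
  expect_equal(sort(unique(lc$per_week$week)), c(1, 2))
  expect_equal(lc$skipped$week, 3)
  w2 <- lc$per_week[lc$per_week$week == 2, ]
  expect_lt(w2$t_p, 0.01)
  w1 <- lc$per_week[lc$per_week$week == 1, ]
  expect_gt(w1$t_p, 0.01)
  expect_true(all(c("pre", "post") %in% lc$prepost$phase))
  # Benjamini-Hochberg column is monotone in raw p
  bh <- adjust_bh(lc)
  expect_true(all(bh$t_p_bh >= bh$t_p - 1e-12))
})
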