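# independent oracle: two-sided t-tail probability by numerically
# integrating the t density (no call into the package's p-value path)
t_tail_numeric <- function(tstat, df) {
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
}

test_that("one-sample t from printed summaries reproduces known p-values", {
  # cohort midline shift 1.57 +/- 0.83 mm, n = 7, vs 0
  expect_equal(round(one_sample_t(mean = 1.57, sd = 0.83, n = 7,
                                  mu0 = 0)$p_value, 4), 0.0024)
  # chronic shift -1.99 +/- 1.00 mm vs 0
  expect_equal(round(one_sample_t(mean = -1.99, sd = 1.00, n = 7,
                                  mu0 = 0)$p_value, 4), 0.0019)
  # hemispheric ratio 115.17 +/- 7.89 % vs no-change 100
  p <- one_sample_t(mean = 115.17, sd = 7.89, n = 7, mu0 = 100)$p_value
  expect_equal(p, 0.00225, tolerance = 1e-2)
})

test_that("one-sample t agrees with numeric integration and stats::t.test", {
  res <- one_sample_t(mean = 15.17, sd = 7.89, n = 7, mu0 = 0)
  expect_equal(res$p_value, t_tail_numeric(res$statistic, 6),
               tolerance = 1e-9)
  withr::with_seed(31, x <- rnorm(12, 1, 2))
  mine <- one_sample_t(x, mu0 = 0.5)
  ref <- stats::t.test(x, mu = 0.5)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p_value, ref$p.value)
  # degenerate and trivial cases
  expect_equal(one_sample_t(mean = 3, sd = 1, n = 5, mu0 = 3)$p_value, 1)
  expect_true(one_sample_t(mean = 3, sd = 0, n = 5)$degenerate)
  expect_error(one_sample_t(mean = 1, sd = 1, n = 1), "n >= 2")
})

test_that("paired t reduces to a one-sample t on the differences", {
  res <- paired_t(c(5, 7, 9), c(3, 4, 5))  # differences 2, 3, 4
  ref <- one_sample_t(mean = 3, sd = 1, n = 3, mu0 = 0)
  expect_equal(res$statistic, ref$statistic)
  expect_equal(res$p_value, ref$p_value)
  x <- c(1, 2, 3, 4)
  same <- paired_t(x, x)
  expect_true(same$degenerate)  # zero-variance differences flagged
  withr::with_seed(32, { a <- rnorm(10); b <- rnorm(10) })
  expect_equal(paired_t(a, b)$p_value,
               stats::t.test(a, b, paired = TRUE)$p.value)
  # NA pairs dropped and counted
  res_na <- paired_t(c(a, NA), c(b, 1))
  expect_equal(res_na$n_dropped, 1)
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("pearson_r matches the closed form, an oracle, and cor.test", {
  x <- c(1.2, 3.4, 2.2, 5.9, 4.4)
  y <- c(0.7, 2.9, 1.8, 6.6, 3.1)
  res <- pearson_r(x, y)
  # brute-force formula, written out independently
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$estimate, r_oracle, tolerance = 1e-12)
  ref <- stats::cor.test(x, y)
  expect_equal(res$estimate, unname(ref$estimate))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$p_value, t_tail_numeric(res$statistic, 3),
               tolerance = 1e-9)
  # exact linear relationships
  expect_equal(pearson_r(x, 2 * x + 1)$estimate, 1)
  expect_equal(pearson_r(x, -x)$estimate, -1)
  expect_true(pearson_r(x, rep(1, 5))$degenerate)
  expect_error(pearson_r(1:2, 1:2), "3 complete")
})

test_that("BH step-up matches hand evaluation and stats::p.adjust", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  withr::with_seed(33, p <- runif(50))
  expect_equal(bh_fdr(p), stats::p.adjust(p, method = "BH"))
  # NAs pass through and do not count toward m
  p_na <- c(0.01, NA, 0.04)
  expect_equal(bh_fdr(p_na), c(0.02, NA, 0.04))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Sidak adjustment follows its closed form", {
  expect_equal(sidak_adjust(0.01, 4), 1 - 0.99^4)
  expect_equal(round(sidak_adjust(0.01, 4), 4), 0.0394)
  expect_equal(sidak_adjust(0, 10), 0)
  expect_equal(sidak_adjust(1, 3), 1)
  expect_equal(sidak_adjust(c(0.05, 0.5), 2), 1 - (1 - c(0.05, 0.5))^2)
})

test_that("tidy/glance return one-row tibbles for test objects", {
  res <- one_sample_t(mean = 1.57, sd = 0.83, n = 7)
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("statistic", "df", "p_value", "estimate", "n",
                     "method", "degenerate"))
})
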