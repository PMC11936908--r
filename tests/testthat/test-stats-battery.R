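test_that("pooled t test matches the hand formula and degenerate cases", {
  same <- pooled_t_test(list(n = 10, mean = 5, sd = 2),
                        list(n = 10, mean = 5, sd = 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  res <- pooled_t_test(list(n = 5, mean = 10, sd = 2),
                       list(n = 5, mean = 8, sd = 2))
  expect_equal(res$statistic, 2 / (2 * sqrt(2 / 5)), tolerance = 1e-12)
  expect_equal(res$statistic, 1.5811, tolerance = 1e-4)
  expect_equal(res$df, 8)
  one <- pooled_t_test(list(n = 5, mean = 10, sd = 2),
                       list(n = 5, mean = 8, sd = 2), tails = "one")
  expect_equal(one$p_value, res$p_value / 2)
  expect_error(pooled_t_test(list(n = 1, mean = 0, sd = 1),
                             list(n = 5, mean = 0, sd = 1)), "at least 2")
})

test_that("summary-triplet and raw-sample t tests coincide", {
  set.seed(601)
  for (i in 1:10) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    from_raw <- pooled_t_test(a, b)
    from_sum <- pooled_t_test(list(n = length(a), mean = mean(a), sd = sd(a)),
                              list(n = length(b), mean = mean(b), sd = sd(b)))
    expect_equal(from_raw$statistic, from_sum$statistic, tolerance = 1e-12)
    expect_equal(from_raw$p_value, from_sum$p_value, tolerance = 1e-12)
    # and both agree with the classical equal-variance test
    expect_equal(from_raw$statistic,
                 unname(t.test(a, b, var.equal = TRUE)$statistic),
                 tolerance = 1e-10)
  }
})

test_that("two-proportion chi-squared matches the 2x2 oracle", {
  flat <- two_proportion_chi2(10, 20, 10, 20)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  expect_equal(two_proportion_chi2(23, 31, 13, 25)$statistic, 2.969004,
               tolerance = 1e-5)
  expect_equal(two_proportion_chi2(23, 31, 13, 25, yates = TRUE)$statistic,
               2.081032, tolerance = 1e-5)
  expect_equal(two_proportion_chi2(23, 31, 13, 25)$df, 1)
  expect_error(two_proportion_chi2(0, 20, 0, 25), "marginal")
  expect_error(two_proportion_chi2(-1, 20, 5, 25), "invalid")
})

test_that("Pearson correlation recovers exact and hand-checked r", {
  x <- c(1, 2, 3, 4, 5)
  perfect <- pearson_correlation(x, 2 * x)
  expect_equal(perfect$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  res <- pearson_correlation(c(1, 2, 3), c(1, 2, 4))
  expect_equal(res$r, 0.981981, tolerance = 1e-6)
  expect_equal(res$df, 1)
  one <- pearson_correlation(c(1, 2, 3, 5), c(2, 2, 4, 4), tails = "one")
  two <- pearson_correlation(c(1, 2, 3, 5), c(2, 2, 4, 4))
  expect_equal(one$p_value, two$p_value / 2)
  expect_error(pearson_correlation(1:5, rep(2, 5)), "zero variance")
  expect_error(pearson_correlation(1:4, 1:5), "unequal")
})

test_that("KS test is 0 on identical samples and 1 on disjoint supports", {
  set.seed(602)
  x <- rnorm(50)
  same <- ks_two_sample(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  disjoint <- ks_two_sample(rnorm(30), rnorm(30) + 100)
  expect_equal(disjoint$statistic, 1)
  expect_lt(disjoint$p_value, 1e-10)
  expect_error(ks_two_sample(1:3, 1:10), "at least 5")
})

test_that("type-I error of the pooled t test is near nominal", {
  set.seed(603)
  reject <- vapply(1:1000, function(i) {
    pooled_t_test(rnorm(15), rnorm(15))$p_value < 0.05
  }, logical(1))
  expect_gt(mean(reject), 0.03)
  expect_lt(mean(reject), 0.07)
})

test_that("batch mode reconstructs comparisons from printed summaries", {
  summaries <- tibble::tibble(
    label = rep(c("dwell", "purchase"), each = 2),
    group = rep(c("WS", "MS"), 2),
    n = c(31, 25, 31, 25),
    mean = c(32.15, 14.69, 265.79, 140.12),
    sd = c(35.37, 10.93, 517.37, 229.42)
  )
  res <- batch_summary_tests(summaries)
  expect_equal(nrow(res), 2)
  direct <- pooled_t_test(list(n = 31, mean = 32.15, sd = 35.37),
                          list(n = 25, mean = 14.69, sd = 10.93))
  expect_equal(res$statistic[res$label == "dwell"], direct$statistic)
  # CSV round trip
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(summaries, path)
  expect_equal(batch_summary_tests(path)$statistic, res$statistic)
  expect_error(batch_summary_tests(summaries[-1, ]), "exactly 2 groups")
})
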