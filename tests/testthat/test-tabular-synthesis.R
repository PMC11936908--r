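test_that("marginal models recover known distributions", {
  set.seed(701)
  tab <- data.frame(x = rnorm(1000))
  model <- fit_synthesizer(tab, gates = NULL)
  expect_equal(model$models$x$mean, 0, tolerance = 0.1)
  expect_equal(model$models$x$sd, 1, tolerance = 0.1)

  tab2 <- data.frame(z = rnorm(1000), b = rbinom(1000, 1, 0.5))
  m2 <- fit_synthesizer(tab2, gates = NULL)
  # b independent of z at rate 0.5: logistic intercept near 0, slope near 0
  expect_equal(unname(coef(m2$models$b$fit)[1]), 0, tolerance = 0.3)
  expect_equal(unname(coef(m2$models$b$fit)[2]), 0, tolerance = 0.3)
})

test_that("deterministic dependence gives near-zero residual scale", {
  tab <- data.frame(x = rnorm(100), y = NA)
  tab$y <- 2 * tab$x
  model <- fit_synthesizer(tab, gates = NULL)
  expect_lt(model$models$y$sigma, 1e-8)
})

test_that("constant columns are reported by name", {
  tab <- data.frame(x = rnorm(50), flat = 7)
  expect_error(fit_synthesizer(tab, gates = NULL), "flat")
  expect_error(fit_synthesizer(data.frame(x = rnorm(5)), gates = NULL),
               "at least 20 rows")
})

test_that("sampling is seed-deterministic and respects gates", {
  s <- labeled_cohort(150, 0, seed = 21)
  vo <- c("age", "loyal", "peak_immersion", "dwell_min", "purchased",
          "purchase_usd")
  model <- fit_synthesizer(s[, vo], visit_order = vo)
  a <- sample_synthetic(model, n = 500, rng_seed = 5)
  b <- sample_synthetic(model, n = 500, rng_seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, sample_synthetic(model, n = 500, rng_seed = 6)))
  # gated amounts: zero exactly when no purchase, positive-tailed otherwise
  expect_true(all(a$purchase_usd[a$purchased == 0] == 0))
  expect_gt(mean(a$purchase_usd[a$purchased == 1] > 0), 0.95)
  expect_true(all(a$purchase_usd >= 0))
})

test_that("large synthetic samples track the training moments", {
  s <- labeled_cohort(2000, 0, seed = 23)
  vo <- c("age", "female", "loyal", "companion", "avg_immersion",
          "peak_immersion", "dwell_min", "purchased", "purchase_usd")
  model <- fit_synthesizer(s[, vo], visit_order = vo)
  syn <- sample_synthetic(model, n = 10000, rng_seed = 31)
  for (v in c("age", "avg_immersion", "peak_immersion", "dwell_min")) {
    expect_equal(mean(syn[[v]]), mean(s[[v]]), tolerance = 0.05)
    expect_equal(sd(syn[[v]]), sd(s[[v]]), tolerance = 0.1)
  }
  expect_equal(mean(syn$purchased), mean(s$purchased), tolerance = 0.05)
})

test_that("earlier marginals are unaffected by later training columns", {
  set.seed(702)
  tab <- data.frame(x = rnorm(200), y = rnorm(200))
  m1 <- fit_synthesizer(tab, visit_order = c("x", "y"), gates = NULL)
  tab2 <- tab
  tab2$y <- sample(tab2$y)
  m2 <- fit_synthesizer(tab2, visit_order = c("x", "y"), gates = NULL)
  expect_identical(m1$models$x, m2$models$x)
  expect_identical(sample_synthetic(m1, 100, 3)$x,
                   sample_synthetic(m2, 100, 3)$x)
})

test_that("fidelity report is exactly zero on identical tables", {
  s <- labeled_cohort(100, 0, seed = 25)
  rep <- fidelity_report(s, s)
  cont <- rep$per_variable[rep$per_variable$type == "continuous", ]
  expect_true(all(cont$ks_statistic == 0))
  expect_true(all(cont$ks_p == 1))
  expect_true(all(cont$quantile_mse == 0))
  expect_identical(rep$overall_mse, 0)
  bin <- rep$per_variable[rep$per_variable$type == "binary", ]
  expect_true(all(bin$rate_diff == 0))
})

test_that("fidelity report flags clearly different distributions", {
  set.seed(703)
  a <- data.frame(x = rnorm(500))
  b <- data.frame(x = rnorm(500, 3))
  rep <- fidelity_report(a, b, exclude = character())
  expect_lt(rep$per_variable$ks_p, 1e-6)
  expect_gt(rep$overall_mse, 1)
  expect_error(fidelity_report(a, data.frame(y = rnorm(10)),
                               exclude = character()), "schemas")
})

test_that("synthesis of the simulated cohort passes the KS screen", {
  s <- labeled_cohort(31, 25, seed = 29, traces = TRUE)
  vo <- c("age", "female", "loyal", "companion", "avg_immersion",
          "peak_immersion", "dwell_min", "purchased", "purchase_usd")
  model <- fit_synthesizer(s[s$store == "WS", vo], visit_order = vo)
  syn <- sample_synthetic(model, n = 10000, rng_seed = 33)
  rep <- fidelity_report(s[s$store == "WS", vo], syn,
                         exclude = character())
  cont <- rep$per_variable[rep$per_variable$type == "continuous", ]
  expect_true(all(cont$ks_p > 0.05))
  expect_lt(rep$overall_mse, 0.5)
})
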