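test_that("Sobel test matches the closed form", {
  null <- sobel_test(0, 0.1, 0.5, 0.1)
  expect_equal(null$statistic, 0)
  expect_equal(null$p_value, 1)
  expect_equal(sobel_test(0.4, 0.05, 0.7, 0.05)$statistic,
               sobel_test(0.7, 0.05, 0.4, 0.05)$statistic)
  res <- sobel_test(0.5, 0.05, 0.3, 0.05)
  expect_equal(res$statistic, 0.15 / sqrt(0.25 * 0.0025 + 0.09 * 0.0025),
               tolerance = 1e-12)
  expect_equal(res$statistic, 5.145, tolerance = 1e-3)
  expect_error(sobel_test(1, 0, 1, 0.1), "positive")
})

test_that("effect decomposition holds exactly and paths match lm", {
  set.seed(801)
  d <- planted_mediation_table(300)
  res <- fit_mediation(d, mediation_spec(bootstrap_reps = 50, rng_seed = 1))
  expect_equal(res$total, res$c_prime + res$indirect, tolerance = 1e-10)
  fa <- lm(dwell_min ~ peak_immersion, data = d)
  fb <- lm(purchase_usd ~ peak_immersion + dwell_min, data = d)
  expect_equal(res$a_path, unname(coef(fa)[2]), tolerance = 1e-10)
  expect_equal(res$b_path, unname(coef(fb)[3]), tolerance = 1e-10)
  expect_equal(res$c_prime, unname(coef(fb)[2]), tolerance = 1e-10)
  expect_equal(res$a_se, unname(sqrt(diag(vcov(fa)))[2]), tolerance = 1e-8)
  expect_equal(res$b_se, unname(sqrt(diag(vcov(fb)))[3]), tolerance = 1e-8)
})

test_that("planted indirect effects are recovered at scale", {
  set.seed(802)
  d <- planted_mediation_table(6000, a = 0.5, b = 0.3)
  res <- fit_mediation(d, mediation_spec(bootstrap_reps = 400, rng_seed = 2))
  expect_equal(res$indirect, 0.15, tolerance = 0.03 / 0.15)
  expect_true(res$indirect_ci[1] < 0.15 && 0.15 < res$indirect_ci[2])
  expect_lt(res$sobel$p_value, 1e-10)
  expect_lt(res$indirect_ci[1], res$indirect_ci[2])
})

test_that("bootstrap CIs tighten roughly as 1/sqrt(n)", {
  set.seed(803)
  w <- purrr::map_dbl(c(500, 2000), function(n) {
    d <- planted_mediation_table(n)
    res <- fit_mediation(d, mediation_spec(bootstrap_reps = 400, rng_seed = 4))
    diff(res$indirect_ci)
  })
  expect_gt(w[1] / w[2], 1.4)
  expect_lt(w[1] / w[2], 3)
})

test_that("standardization matches manual z-scoring", {
  set.seed(804)
  d <- planted_mediation_table(500)
  std <- fit_mediation(d, mediation_spec(standardize = TRUE,
                                         bootstrap_reps = 50, rng_seed = 5))
  dz <- d
  dz[] <- lapply(dz, function(x) as.numeric(scale(x)))
  manual <- fit_mediation(dz, mediation_spec(bootstrap_reps = 50, rng_seed = 5))
  expect_equal(std$a_path, manual$a_path, tolerance = 1e-12)
  expect_equal(std$indirect, manual$indirect, tolerance = 1e-12)
  # affine rescaling of the predictor rescales a by 1/k, leaves a*b/sd ratios
  dk <- d
  dk$peak_immersion <- 100 * dk$peak_immersion
  resk <- fit_mediation(dk, mediation_spec(bootstrap_reps = 50, rng_seed = 5))
  res <- fit_mediation(d, mediation_spec(bootstrap_reps = 50, rng_seed = 5))
  expect_equal(resk$a_path, res$a_path / 100, tolerance = 1e-10)
  expect_equal(resk$b_path, res$b_path, tolerance = 1e-10)
})

test_that("covariates enter both equations and collinearity is caught", {
  set.seed(805)
  d <- planted_mediation_table(400)
  d$loyal <- rbinom(400, 1, 0.5)
  d$companion <- rbinom(400, 1, 0.3)
  res <- fit_mediation(d, mediation_spec(covariates = c("loyal", "companion"),
                                         bootstrap_reps = 50, rng_seed = 6))
  expect_s3_class(res$sobel, "tbl_df")
  d$dup <- d$loyal
  expect_error(
    fit_mediation(d, mediation_spec(covariates = c("loyal", "dup"),
                                    bootstrap_reps = 50, rng_seed = 6)),
    "collinear"
  )
  expect_error(fit_mediation(d[1:10, ], mediation_spec(bootstrap_reps = 10)),
               "at least 20")
  expect_error(fit_mediation(d, mediation_spec(predictor = "nope")),
               "missing columns")
})

test_that("mediation JSON serialization preserves the estimates", {
  set.seed(806)
  d <- planted_mediation_table(200)
  res <- fit_mediation(d, mediation_spec(bootstrap_reps = 50, rng_seed = 7))
  path <- withr::local_tempfile(fileext = ".json")
  write_mediation_json(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$indirect, res$indirect, tolerance = 1e-12)
  expect_equal(back$indirect_ci, unname(res$indirect_ci), tolerance = 1e-12)
  expect_equal(back$spec$bootstrap_reps, 50)
})
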