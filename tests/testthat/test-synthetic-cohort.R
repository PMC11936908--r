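test_that("trace generation is seed-deterministic and well-formed", {
  prof <- default_store_profiles()$WS
  a <- generate_trace(2, 300, prof, rng_seed = 42)
  b <- generate_trace(2, 300, prof, rng_seed = 42)
  c <- generate_trace(2, 300, prof, rng_seed = 43)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_equal(length(a$values), 300)
  expect_equal(a$times, 0:299)
  expect_true(all(a$values > 0))
  expect_error(generate_trace(2, 30, prof, 1), "at least 60")
})

test_that("ablating bursts decouples peak Immersion from experiential value", {
  prof <- default_store_profiles()$WS
  flat_prof <- do.call(store_profile,
                       modifyList(unclass(prof),
                                  list(burst_amplitude_scale = 0)))
  e_grid <- rep(c(0.8, 2, 5), each = 15)
  flat <- purrr::map2_dbl(e_grid, seq_along(e_grid), function(e, i) {
    peak_immersion(generate_trace(e, 600, flat_prof, rng_seed = i))
  })
  bursty <- purrr::map2_dbl(e_grid, seq_along(e_grid), function(e, i) {
    peak_immersion(generate_trace(e, 600, prof, rng_seed = 1000 + i))
  })
  # without bursts the statistic sits in the pure-Gaussian regime (the
  # above-threshold mass of near-normal noise), away from the calibrated
  # burst-driven regime, and no longer tracks e
  expect_gt(abs(mean(flat) - mean(bursty)), 0.03)
  expect_lt(abs(cor(e_grid, flat)), 0.25)
  expect_gt(cor(e_grid, bursty), 0.25)
})

test_that("cohort generation is reproducible and respects invariants", {
  profs <- default_store_profiles(n_ws = 15, n_ms = 10)
  a <- generate_cohort(profs, rng_seed = 9)
  b <- generate_cohort(profs, rng_seed = 9)
  expect_identical(a$sessions, b$sessions)
  expect_identical(purrr::map(a$traces, "values"),
                   purrr::map(b$traces, "values"))
  s <- a$sessions
  expect_equal(nrow(s), 25)
  expect_setequal(unique(s$store), c("WS", "MS"))
  expect_true(all(s$dwell_min > 0))
  expect_true(all(s$purchase_usd >= 0))
  expect_true(all(s$female %in% 0:1))
  expect_named(a$traces, s$session_id)
  # trace durations follow dwell
  lens <- purrr::map_int(a$traces, ~ length(.x$values))
  expect_equal(unname(lens), pmax(60, round(60 * s$dwell_min)))
})

test_that("an empty profile yields an empty cohort", {
  profs <- default_store_profiles(n_ws = 0, n_ms = 0)
  co <- generate_cohort(profs, rng_seed = 1)
  expect_equal(nrow(co$sessions), 0)
  expect_length(co$traces, 0)
  expect_error(generate_cohort(list(), 1), "non-empty")
})

test_that("behavioral links are monotone in the latent experiential value", {
  profs <- default_store_profiles(n_ws = 2000, n_ms = 0)
  s <- generate_cohort(profs["WS"], rng_seed = 31, traces = FALSE)$sessions
  expect_gt(cor(s$latent_e, s$dwell_min, method = "spearman"), 0.5)
  expect_gt(cor(s$latent_e, s$purchase_usd, method = "spearman"), 0.3)
  bins <- cut(s$latent_e, quantile(s$latent_e, seq(0, 1, 0.2)),
              include.lowest = TRUE)
  expect_true(all(diff(tapply(s$dwell_min, bins, mean)) > 0))
  expect_true(all(diff(tapply(s$purchase_usd > 0, bins, mean)) > 0))
})

test_that("default profiles reproduce the observed store summaries", {
  s <- generate_cohort(default_store_profiles(1200, 1200), rng_seed = 77,
                       traces = FALSE)$sessions
  ws <- s[s$store == "WS", ]; ms <- s[s$store == "MS", ]
  expect_equal(mean(ws$dwell_min), 32.15, tolerance = 0.15)
  expect_equal(mean(ms$dwell_min), 14.69, tolerance = 0.15)
  expect_equal(mean(ws$purchase_usd > 0), 0.73, tolerance = 0.1)
  expect_equal(mean(ms$purchase_usd > 0), 0.52, tolerance = 0.12)
  expect_equal(mean(ws$female), 0.9, tolerance = 0.05)
  expect_equal(mean(ws$age), 48.83, tolerance = 0.05)
})

test_that("simulated traces reproduce the observed Immersion summaries", {
  co <- generate_cohort(default_store_profiles(120, 120), rng_seed = 19)
  m <- session_metrics_table(co$traces)
  m$store <- co$sessions$store[match(m$session_id, co$sessions$session_id)]
  ws <- m[m$store == "WS", ]; ms <- m[m$store == "MS", ]
  expect_equal(mean(ws$peak_immersion), 0.2418, tolerance = 0.02 / 0.2418)
  expect_equal(mean(ms$peak_immersion), 0.255, tolerance = 0.025 / 0.255)
  expect_equal(mean(ws$avg_immersion), 4.422, tolerance = 0.2 / 4.422)
  expect_equal(mean(ms$avg_immersion), 4.486, tolerance = 0.2 / 4.486)
  # individual sessions stay in the plausible band
  expect_gt(mean(ws$peak_immersion > 0.15 & ws$peak_immersion < 0.35), 0.95)
})

test_that("profile validation rejects out-of-range parameters", {
  expect_error(store_profile("X", 10, 0, 0.5, loyal_rate = 1.4), "rates")
  expect_error(store_profile("X", 10, 0, -0.5), "positive")
  expect_error(store_profile("X", 10, 0, 0.5, ar_coefficient = 1), "ar_coefficient")
  expect_error(store_profile("X", -1, 0, 0.5), "non-negative")
})

test_that("session CSV round-trips and hides the latent value by default", {
  co <- generate_cohort(default_store_profiles(12, 0), rng_seed = 3,
                        traces = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(co$sessions, path)
  back <- read_sessions(path)
  expect_false("latent_e" %in% names(back))
  expect_equal(back$dwell_min, co$sessions$dwell_min)
  expect_identical(readr::read_file(path),
                   { write_sessions(co$sessions, path); readr::read_file(path) })
})
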