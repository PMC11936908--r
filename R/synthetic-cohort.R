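#' Store simulation profile
#'
#' Bundles every parameter needed to simulate one store arm of a two-store
#' field study: the latent experiential-value distribution, the Immersion
#' trace process of the sales associate, the behavioral links from
#' experiential value to dwell time and purchases, and the customer covariate
#' distributions. [default_store_profiles()] returns profiles calibrated to
#' the observed summaries of the women's-clothing (WS) and men's-clothing
#' (MS) store arms.
#'
#' @param store_label `"WS"` or `"MS"` (any short label is accepted).
#' @param n_sessions Number of shopper sessions to simulate.
#' @param e_lognormal_mu,e_lognormal_sigma Log-scale mean and SD of the latent
#'   experiential value `e` (lognormal across shoppers).
#' @param kappa Minutes of dwell per unit `e` (the proportionality linking
#'   experiential value to time in store).
#' @param dwell_noise_sigma Log-scale SD of multiplicative noise on dwell time.
#' @param purchase_income Currency scale `M` of the budget; expected spending
#'   conditional on purchase is `M * e/(1+e)` (price normalized to 1).
#' @param purchase_amount_sigma Log-scale SD of multiplicative noise on the
#'   purchase amount (reproduces the heavy right tail of luxury spending).
#' @param purchase_prob_intercept,purchase_prob_slope Logistic link from `e`
#'   to purchase incidence: `P(buy) = plogis(intercept + slope * e)`.
#' @param loyal_rate,companion_rate,female_rate Bernoulli rates of the
#'   return-customer flag, the accompanied-shopper flag, and female sex.
#' @param age_mu,age_sigma Customer age distribution (years, truncated to
#'   18-90).
#' @param baseline_mu Store-level mean of the associate's baseline Immersion
#'   (platform units).
#' @param session_mu_sigma SD of the per-session baseline offset (captures
#'   session-to-session variation in the associate's tonic state).
#' @param baseline_sigma Stationary SD of the within-session AR(1)
#'   fluctuation around the session baseline.
#' @param ar_coefficient AR(1) coefficient of the within-session fluctuation.
#' @param burst_rate_per_min Expected Immersion burst episodes per minute at
#'   the store's reference experiential value.
#' @param burst_len_mean_sec Mean burst episode duration in seconds
#'   (geometric).
#' @param burst_amplitude_scale Mean burst amplitude (Immersion units above
#'   baseline).
#' @param burst_e_gain Gain of the (damped) link from a shopper's `e` to that
#'   session's burst rate; 0 disconnects Peak Immersion from `e`.
#' @return A `store_profile` list.
#' @export
store_profile <- function(store_label,
                          n_sessions,
                          e_lognormal_mu,
                          e_lognormal_sigma,
                          kappa = 10,
                          dwell_noise_sigma = 0.5,
                          purchase_income = 350,
                          purchase_amount_sigma = 0.9,
                          purchase_prob_intercept = -1.2,
                          purchase_prob_slope = 1,
                          loyal_rate = 0.5,
                          companion_rate = 0.3,
                          age_mu = 50,
                          age_sigma = 12,
                          female_rate = 0.5,
                          baseline_mu = 4.2,
                          session_mu_sigma = 0.2,
                          baseline_sigma = 0.12,
                          ar_coefficient = 0.9,
                          burst_rate_per_min = 1.5,
                          burst_len_mean_sec = 8,
                          burst_amplitude_scale = 1,
                          burst_e_gain = 0.5) {
  p <- as.list(environment())
  rates <- c(p$loyal_rate, p$companion_rate, p$female_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]", call. = FALSE)
  }
  scales <- c(p$kappa, p$purchase_income, p$baseline_mu, p$baseline_sigma,
              p$burst_len_mean_sec, p$e_lognormal_sigma)
  if (any(scales <= 0)) stop("scale parameters must be positive", call. = FALSE)
  if (p$ar_coefficient < 0 || p$ar_coefficient >= 1) {
    stop("`ar_coefficient` must lie in [0, 1)", call. = FALSE)
  }
  if (p$n_sessions < 0) stop("`n_sessions` must be non-negative", call. = FALSE)
  structure(p, class = "store_profile")
}

#' Calibrated default profiles for the two store arms
#'
#' Returns WS and MS profiles whose simulated cohorts approximate the
#' observed store summaries: dwell time (WS about 32 min with a heavy tail,
#' MS about 15 min), purchase frequency (about 0.73 vs 0.52), average
#' associate Immersion near 4.42/4.49 platform units, and mean Peak Immersion
#' near 0.242 (WS) and 0.255 (MS). Session counts default to the field-study
#' arms (WS n = 31, MS n = 25).
#'
#' @param n_ws,n_ms Session counts for the two arms.
#' @return A named list of two `store_profile` objects.
#' @export
default_store_profiles <- function(n_ws = 31, n_ms = 25) {
  list(
    WS = store_profile(
      store_label = "WS", n_sessions = n_ws,
      e_lognormal_mu = 0.77, e_lognormal_sigma = 0.70,
      kappa = 10, dwell_noise_sigma = 0.55,
      purchase_income = 355, purchase_amount_sigma = 0.90,
      purchase_prob_intercept = -1.05, purchase_prob_slope = 1,
      loyal_rate = 0.43, companion_rate = 0.35,
      age_mu = 48.83, age_sigma = 11.88, female_rate = 0.90,
      baseline_mu = 4.20, session_mu_sigma = 0.20,
      baseline_sigma = 0.12, ar_coefficient = 0.9,
      burst_rate_per_min = 6.5, burst_len_mean_sec = 2,
      burst_amplitude_scale = 1.05, burst_e_gain = 0.5
    ),
    MS = store_profile(
      store_label = "MS", n_sessions = n_ms,
      e_lognormal_mu = 0.164, e_lognormal_sigma = 0.55,
      kappa = 10, dwell_noise_sigma = 0.37,
      purchase_income = 400, purchase_amount_sigma = 0.50,
      purchase_prob_intercept = -2.45, purchase_prob_slope = 2,
      loyal_rate = 0.52, companion_rate = 0.30,
      age_mu = 51.0, age_sigma = 13.5, female_rate = 0.52,
      baseline_mu = 4.22, session_mu_sigma = 0.22,
      baseline_sigma = 0.12, ar_coefficient = 0.9,
      burst_rate_per_min = 6.9, burst_len_mean_sec = 2,
      burst_amplitude_scale = 1.15, burst_e_gain = 0.5
    )
  )
}

# Run code with a local, seeded RNG stream and restore the caller's state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one sales-associate Immersion trace
#'
#' The trace is a per-session baseline offset plus a stationary AR(1)
#' fluctuation, overlaid with non-negative burst episodes (geometric
#' durations, gamma amplitudes) whose rate increases with the shopper's
#' experiential value `e`. Bursts are what drive the Peak Immersion
#' statistic; setting `burst_amplitude_scale = 0` in the profile ablates the
#' peak signal down to baseline noise.
#'
#' @param e Latent experiential value of the shopper being served.
#' @param duration_sec Session duration in seconds (>= 60; 1 Hz sampling).
#' @param profile A [store_profile()].
#' @param rng_seed Integer seed; the same seed reproduces the trace exactly.
#' @param session_id Identifier for the generated trace.
#' @return An [immersion_trace()] of length `duration_sec`.
#' @export
generate_trace <- function(e, duration_sec, profile, rng_seed,
                           session_id = "sim") {
  stopifnot(inherits(profile, "store_profile"))
  duration_sec <- as.integer(round(duration_sec))
  if (duration_sec < 60) {
    stop("`duration_sec` must be at least 60 s", call. = FALSE)
  }
  values <- with_local_seed(rng_seed, {
    n <- duration_sec
    mu_i <- stats::rnorm(1, profile$baseline_mu, profile$session_mu_sigma)
    phi <- profile$ar_coefficient
    innov_sd <- profile$baseline_sigma * sqrt(1 - phi^2)
    ar <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                   method = "recursive",
                                   init = stats::rnorm(1, 0, profile$baseline_sigma)))
    # burst rate scales (with damped gain) in the shopper's budget share
    # e/(1+e), referenced to the store's typical share, so Peak Immersion is a
    # gentle monotone correlate of e
    u <- e / (1 + e)
    u_ref <- local({
      em <- exp(profile$e_lognormal_mu)
      em / (1 + em)
    })
    rate_factor <- max(0.1, 1 + profile$burst_e_gain * (u / u_ref - 1))
    n_episodes <- stats::rpois(
      1, profile$burst_rate_per_min * rate_factor * n / 60
    )
    burst <- numeric(n)
    if (n_episodes > 0 && profile$burst_amplitude_scale > 0) {
      starts <- sample.int(n, n_episodes, replace = TRUE)
      lens <- 1 + stats::rgeom(n_episodes, 1 / profile$burst_len_mean_sec)
      amps <- profile$burst_amplitude_scale * stats::rgamma(n_episodes, 16, 16)
      for (k in seq_len(n_episodes)) {
        idx <- starts[k]:min(n, starts[k] + lens[k] - 1)
        burst[idx] <- burst[idx] + amps[k]
      }
    }
    pmax(mu_i + ar + burst, 0.05)
  })
  immersion_trace(session_id, seq_len(duration_sec) - 1, values)
}

#' Simulate a multi-store shopper cohort with associate traces
#'
#' For each session a latent experiential value `e` is drawn lognormally;
#' dwell time is `kappa * e` with multiplicative lognormal noise (value of
#' the experience proportional to time in store), purchase incidence follows
#' a logistic link in `e`, the purchase amount given incidence is the
#' Cobb-Douglas spending share `M * e/(1+e)` with lognormal noise (price
#' normalized to 1), and the associate's Immersion trace is generated over
#' the session duration with burst activity tied to `e`.
#'
#' @param profiles A list of [store_profile()] objects (e.g.
#'   [default_store_profiles()]).
#' @param rng_seed Integer master seed; per-session trace seeds are derived
#'   from it deterministically.
#' @param traces Generate the 1 Hz traces as well (set `FALSE` for fast
#'   table-only simulation).
#' @param keep_latent Keep the generating `latent_e` column (used for
#'   parameter-recovery checks; excluded from CSV output by default).
#' @return A list with `sessions` (tibble: session_id, store, age, female,
#'   loyal, companion, dwell_min, purchase_usd, and optionally latent_e) and
#'   `traces` (named list of `immersion_trace`, or `NULL`).
#' @export
generate_cohort <- function(profiles, rng_seed = 1969, traces = TRUE,
                            keep_latent = TRUE) {
  if (length(profiles) == 0) stop("`profiles` must be non-empty", call. = FALSE)
  purrr::walk(profiles, function(p) stopifnot(inherits(p, "store_profile")))
  out <- with_local_seed(rng_seed, {
    trace_seeds <- list()
    tabs <- purrr::imap(profiles, function(p, nm) {
      n <- p$n_sessions
      if (n == 0) {
        return(tibble::tibble(
          session_id = character(), store = character(), age = numeric(),
          female = integer(), loyal = integer(), companion = integer(),
          dwell_min = numeric(), purchase_usd = numeric(), latent_e = numeric()
        ))
      }
      e <- stats::rlnorm(n, p$e_lognormal_mu, p$e_lognormal_sigma)
      dwell <- pmax(
        1.5,
        predicted_dwell(e, p$kappa) * exp(stats::rnorm(n, 0, p$dwell_noise_sigma))
      )
      buy <- stats::rbinom(
        n, 1, stats::plogis(p$purchase_prob_intercept + p$purchase_prob_slope * e)
      )
      amount <- buy * p$purchase_income * e / (1 + e) *
        exp(stats::rnorm(n, 0, p$purchase_amount_sigma))
      tibble::tibble(
        session_id = sprintf("%s_%03d", p$store_label, seq_len(n)),
        store = p$store_label,
        age = pmin(90, pmax(18, round(stats::rnorm(n, p$age_mu, p$age_sigma)))),
        female = stats::rbinom(n, 1, p$female_rate),
        loyal = stats::rbinom(n, 1, p$loyal_rate),
        companion = stats::rbinom(n, 1, p$companion_rate),
        dwell_min = dwell,
        purchase_usd = round(amount, 2),
        latent_e = e
      )
    })
    sessions <- dplyr::bind_rows(tabs)
    seeds <- if (nrow(sessions) > 0) {
      sample.int(.Machine$integer.max - 1, nrow(sessions))
    } else integer()
    list(sessions = sessions, seeds = seeds)
  })
  sessions <- out$sessions
  trace_list <- NULL
  if (traces && nrow(sessions) > 0) {
    prof_by_store <- stats::setNames(profiles, purrr::map_chr(profiles, "store_label"))
    trace_list <- purrr::pmap(
      list(sessions$latent_e, sessions$dwell_min, sessions$store,
           out$seeds, sessions$session_id),
      function(e, dwell, store, seed, sid) {
        generate_trace(e, max(60, round(60 * dwell)), prof_by_store[[store]],
                       rng_seed = seed, session_id = sid)
      }
    )
    names(trace_list) <- sessions$session_id
  } else if (traces) {
    trace_list <- list()
  }
  if (!keep_latent) sessions$latent_e <- NULL
  list(sessions = sessions, traces = trace_list)
}

#' Write a simulated session table as CSV
#'
#' @param sessions Session tibble from [generate_cohort()].
#' @param path Output path.
#' @param keep_latent Include the generating `latent_e` column (off by
#'   default: downstream stages must not see the latent value).
#' @return `path`, invisibly.
#' @export
write_sessions <- function(sessions, path, keep_latent = FALSE) {
  if (!keep_latent && "latent_e" %in% names(sessions)) {
    sessions$latent_e <- NULL
  }
  readr::write_csv(sessions, path)
  invisible(path)
}

#' Read a session table written by [write_sessions()]
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_sessions <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    session_id = readr::col_character(),
    store = readr::col_character(),
    .default = readr::col_double()
  ))
}
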