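# Independent brute-force oracles and small fixture builders.

# Explicit-loop Peak Immersion: median, n-1 SD, strict > threshold, value sum.
peak_oracle <- function(values) {
  n <- length(values)
  s <- sort(values)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  mu <- sum(values) / n
  ss <- 0
  for (v in values) ss <- ss + (v - mu)^2
  thr <- med + 0.5 * sqrt(ss / (n - 1))
  num <- 0
  tot <- 0
  for (v in values) {
    tot <- tot + v
    if (v > thr) num <- num + v
  }
  num / tot
}

# Pairwise-comparison AUC with ties counted half.
auc_oracle <- function(labels, probs) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

make_trace <- function(values, id = "t") {
  immersion_trace(id, seq_along(values) - 1, values)
}

random_trace <- function(len, id = "r") {
  make_trace(exp(rnorm(len, log(4), 0.4)), id = id)
}

# Cohort with known mediation structure: M = a*X + noise, Y = b*M + c*X + noise.
planted_mediation_table <- function(n, a = 0.5, b = 0.3, c_direct = 0.1,
                                    noise_sd = 1) {
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, noise_sd)
  y <- b * m + c_direct * x + rnorm(n, 0, noise_sd)
  tibble::tibble(peak_immersion = x, dwell_min = m, purchase_usd = y)
}

# Fast table-only two-store cohort joined with simulated Immersion metrics.
labeled_cohort <- function(n_ws = 200, n_ms = 200, seed = 11, traces = FALSE) {
  co <- generate_cohort(default_store_profiles(n_ws, n_ms), rng_seed = seed,
                        traces = traces)
  s <- co$sessions
  if (traces) {
    m <- session_metrics_table(co$traces)
    s <- dplyr::inner_join(s, m[, c("session_id", "avg_immersion",
                                    "peak_immersion")], by = "session_id")
  } else {
    # stand-in metrics correlated with the latent value, for tests that only
    # need plausible columns rather than the trace process
    s$avg_immersion <- 4.4 + 0.1 * scale(log(s$latent_e))[, 1] + rnorm(nrow(s), 0, 0.2)
    s$peak_immersion <- plogis(-1.1 + 0.3 * log(s$latent_e) + rnorm(nrow(s), 0, 0.1)) / 2
  }
  discretize_purchase(s)
}

tiny_grid <- function() {
  list(
    random_forest = list(ntree = 100),
    gradient_boosting = list(eta = 0.3, max_depth = 3, nrounds = 50),
    extra_trees = list(num.trees = 100, min.node.size = 10)
  )
}
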