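#' Specification of a mediation analysis
#'
#' The default specification encodes the causal chain under study: the sales
#' associate's Peak Immersion (predictor) raises the customer's dwell time
#' (mediator), which in turn raises the purchase amount (outcome).
#'
#' @param predictor,mediator,outcome Column names in the analysis table.
#' @param covariates Optional covariate columns entering both equations
#'   (typically `loyal` and `companion`).
#' @param standardize Z-score predictor, mediator and outcome before fitting.
#' @param bootstrap_reps Bootstrap resamples for percentile CIs; use at least
#'   1000 for reported intervals (default 5000). Smaller values are accepted
#'   for simulation studies.
#' @param rng_seed Seed for the bootstrap.
#' @return A `mediation_spec` list.
#' @export
mediation_spec <- function(predictor = "peak_immersion",
                           mediator = "dwell_min",
                           outcome = "purchase_usd",
                           covariates = character(),
                           standardize = FALSE,
                           bootstrap_reps = 5000,
                           rng_seed = 1969) {
  if (bootstrap_reps < 1) stop("`bootstrap_reps` must be positive", call. = FALSE)
  structure(list(predictor = predictor, mediator = mediator, outcome = outcome,
                 covariates = covariates, standardize = standardize,
                 bootstrap_reps = bootstrap_reps, rng_seed = rng_seed),
            class = "mediation_spec")
}

#' Fit the mediation model with bootstrap indirect-effect inference
#'
#' Two linear equations estimated by least squares (the maximum-likelihood
#' estimator under Gaussian errors): `mediator ~ predictor (+ covariates)`
#' gives the a path, and `outcome ~ predictor + mediator (+ covariates)`
#' gives the b path and the direct effect c'. The indirect effect is `a * b`,
#' with a percentile bootstrap CI over row resampling and a closed-form Sobel
#' test as complement. The linear decomposition `total = c' + a * b` holds
#' exactly.
#'
#' @param table Data frame with the spec's columns, at least 20 complete rows
#'   (enough for the store-stratified small-sample arms; results at such
#'   sizes are low-powered).
#' @param spec A [mediation_spec()].
#' @return A `mediation_result` list: `a_path`, `b_path`, `c_prime`,
#'   `indirect`, `total`, standard errors and p-values per path, percentile
#'   CIs (`indirect_ci`, `c_prime_ci`), `sobel` (z and p), `n`, and the spec.
#' @export
fit_mediation <- function(table, spec = mediation_spec()) {
  stopifnot(inherits(spec, "mediation_spec"))
  cols <- c(spec$predictor, spec$mediator, spec$outcome, spec$covariates)
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- as.data.frame(table)[, cols, drop = FALSE]
  if (anyNA(d)) stop("missing values in analysis columns", call. = FALSE)
  if (nrow(d) < 20) stop("need at least 20 rows", call. = FALSE)
  if (spec$standardize) {
    for (v in c(spec$predictor, spec$mediator, spec$outcome)) {
      d[[v]] <- as.numeric(scale(d[[v]]))
    }
  }
  X <- d[[spec$predictor]]
  M <- d[[spec$mediator]]
  Y <- d[[spec$outcome]]
  Z <- if (length(spec$covariates)) {
    as.matrix(d[, spec$covariates, drop = FALSE])
  } else NULL
  dm_a <- cbind(1, X, Z)
  dm_b <- cbind(1, X, M, Z)
  if (qr(dm_b)$rank < ncol(dm_b)) {
    stop("collinear design: check covariates ",
         paste(spec$covariates, collapse = ", "), call. = FALSE)
  }
  fa <- ols_fit(dm_a, M)
  fb <- ols_fit(dm_b, Y)
  a <- fa$coef[2]; se_a <- fa$se[2]
  b <- fb$coef[3]; se_b <- fb$se[3]
  c_prime <- fb$coef[2]; se_c <- fb$se[2]
  indirect <- a * b
  boot <- with_local_seed(spec$rng_seed, {
    n <- length(Y)
    vapply(seq_len(spec$bootstrap_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      ca <- stats::.lm.fit(dm_a[idx, , drop = FALSE], M[idx])$coefficients
      cb <- stats::.lm.fit(dm_b[idx, , drop = FALSE], Y[idx])$coefficients
      c(ca[2] * cb[3], cb[2])
    }, numeric(2))
  })
  structure(list(
    a_path = unname(a), a_se = unname(se_a), a_p = unname(fa$p[2]),
    b_path = unname(b), b_se = unname(se_b), b_p = unname(fb$p[3]),
    c_prime = unname(c_prime), c_prime_se = unname(se_c),
    c_prime_p = unname(fb$p[2]),
    indirect = unname(indirect),
    total = unname(c_prime + indirect),
    indirect_ci = unname(stats::quantile(boot[1, ], c(0.025, 0.975))),
    c_prime_ci = unname(stats::quantile(boot[2, ], c(0.025, 0.975))),
    sobel = sobel_test(a, se_a, b, se_b),
    n = length(Y),
    spec = spec
  ), class = "mediation_result")
}

ols_fit <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  rdf <- length(y) - fit$rank
  s2 <- sum(fit$residuals^2) / rdf
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * s2)
  tval <- fit$coefficients / se
  list(coef = fit$coefficients, se = se,
       p = 2 * stats::pt(-abs(tval), rdf))
}

#' Sobel test for an indirect effect
#'
#' Closed-form normal-theory complement to the bootstrap:
#' `z = a*b / sqrt(a^2 se_b^2 + b^2 se_a^2)`, two-tailed normal p.
#'
#' @param a,b Path estimates.
#' @param se_a,se_b Their standard errors (positive).
#' @return A one-row tibble: `statistic` (z), `p_value`.
#' @export
sobel_test <- function(a, se_a, b, se_b) {
  if (se_a <= 0 || se_b <= 0) stop("standard errors must be positive",
                                   call. = FALSE)
  denom <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  z <- if (denom == 0) 0 else a * b / denom
  test_result(unname(z), NA_real_, 2 * stats::pnorm(-abs(z)), "two")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result> n =", x$n, "\n")
  cat(sprintf("  a  (%s -> %s): %.4g (se %.3g, p %.3g)\n",
              x$spec$predictor, x$spec$mediator, x$a_path, x$a_se, x$a_p))
  cat(sprintf("  b  (%s -> %s | %s): %.4g (se %.3g, p %.3g)\n",
              x$spec$mediator, x$spec$outcome, x$spec$predictor,
              x$b_path, x$b_se, x$b_p))
  cat(sprintf("  c' (direct): %.4g (se %.3g, p %.3g)\n",
              x$c_prime, x$c_prime_se, x$c_prime_p))
  cat(sprintf("  indirect a*b: %.4g  [%.4g, %.4g] (95%% percentile bootstrap)\n",
              x$indirect, x$indirect_ci[1], x$indirect_ci[2]))
  cat(sprintf("  Sobel z: %.3f (p %.3g); total: %.4g\n",
              x$sobel$statistic, x$sobel$p_value, x$total))
  invisible(x)
}

#' Serialize a mediation result as JSON
#'
#' @param result A `mediation_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mediation_json <- function(result, path) {
  out <- result[setdiff(names(result), "spec")]
  out$sobel <- as.list(out$sobel)
  out$spec <- unclass(result$spec)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
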