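#' Fit a sequential parametric synthesizer to a session table
#'
#' Implements parametric joint-distribution synthesis: variables are visited
#' in a fixed causal order; the first is modeled marginally and each later
#' variable is fitted conditionally on all earlier ones (normal-linear for
#' continuous variables, logistic for binary flags, empirical/multinomial for
#' categorical labels). Sampling from the fitted chain then reproduces the
#' joint distribution, allowing a small observed table to be expanded into an
#' arbitrarily large synthetic one.
#'
#' Heavy-tailed variables can be `log1p`-transformed before the normal-linear
#' fit and back-transformed on sampling. A variable may be *gated* by an
#' earlier binary variable (e.g. purchase amount gated by purchase
#' incidence): its conditional model is fitted on the rows where the gate is
#' 1 and sampled as 0 elsewhere, giving zero-inflated amounts.
#'
#' @param table A complete data frame with at least 20 rows.
#' @param visit_order Character vector of column names; every synthesized
#'   variable appears exactly once. Defaults to all columns in table order.
#' @param log_transform Columns to `log1p`-transform before normal-linear
#'   fitting.
#' @param gates Named character vector mapping a column to the earlier binary
#'   column that gates it.
#' @return A `synthesis_model` object.
#' @export
fit_synthesizer <- function(table,
                            visit_order = NULL,
                            log_transform = intersect(
                              c("dwell_min", "purchase_usd"), names(table)
                            ),
                            gates = c(purchase_usd = "purchased")) {
  table <- as.data.frame(table)
  if (nrow(table) < 20) stop("need at least 20 rows to fit", call. = FALSE)
  if (anyNA(table)) stop("table must be complete (no missing values)",
                         call. = FALSE)
  if (is.null(visit_order)) visit_order <- names(table)
  if (anyDuplicated(visit_order) || !all(visit_order %in% names(table))) {
    stop("`visit_order` must list existing columns, each exactly once",
         call. = FALSE)
  }
  gates <- gates[names(gates) %in% visit_order]
  models <- list()
  for (k in seq_along(visit_order)) {
    var <- visit_order[k]
    earlier <- visit_order[seq_len(k - 1)]
    x <- table[[var]]
    type <- column_type(x)
    # a constant binary flag is a valid (degenerate) Bernoulli; a constant
    # continuous variable has no fittable conditional model
    if (type == "continuous" && stats::sd(x) == 0) {
      stop("column '", var, "' is constant; degenerate synthesis model",
           call. = FALSE)
    }
    gate <- unname(gates[var])
    fit_rows <- if (!is.null(gate) && !is.na(gate)) {
      if (!gate %in% earlier) {
        stop("gate '", gate, "' must precede '", var, "' in visit_order",
             call. = FALSE)
      }
      table[[gate]] == 1
    } else rep(TRUE, nrow(table))
    # the gate is constant inside the gated subset, and other predictors may
    # degenerate there too; drop them from the conditional fit
    preds <- setdiff(earlier, gate)
    preds <- preds[vapply(preds, function(p) {
      v <- table[fit_rows, p]
      is.character(v) || is.factor(v) || stats::sd(as.numeric(v)) > 0
    }, logical(1))]
    d <- table[fit_rows, c(var, preds), drop = FALSE]
    use_log <- var %in% log_transform && type == "continuous"
    if (use_log) d[[var]] <- log1p(d[[var]])
    models[[var]] <- c(
      fit_conditional(d, var, preds, type),
      list(gate = if (is.null(gate)) NA_character_ else gate,
           log_transform = use_log)
    )
  }
  structure(list(visit_order = visit_order, models = models,
                 n_train = nrow(table)),
            class = "synthesis_model")
}

column_type <- function(x) {
  if (is.character(x) || is.factor(x)) return("categorical")
  ux <- unique(x)
  if (all(ux %in% c(0, 1))) return("binary")
  "continuous"
}

fit_conditional <- function(d, var, earlier, type) {
  if (length(earlier) == 0) {
    return(switch(type,
      continuous = list(type = type, marginal = TRUE,
                        mean = mean(d[[var]]), sd = stats::sd(d[[var]])),
      binary = list(type = type, marginal = TRUE, rate = mean(d[[var]])),
      categorical = list(type = type, marginal = TRUE,
                         levels = sort(unique(d[[var]])),
                         probs = as.numeric(prop.table(table(d[[var]])[
                           sort(unique(d[[var]]))])))
    ))
  }
  fml <- stats::reformulate(earlier, response = var)
  switch(type,
    continuous = {
      fit <- stats::lm(fml, data = d)
      sigma <- sqrt(sum(stats::residuals(fit)^2) /
                      max(1, stats::df.residual(fit)))
      list(type = type, marginal = FALSE, fit = strip_lm(fit), sigma = sigma)
    },
    binary = {
      if (stats::sd(d[[var]]) == 0) {
        list(type = type, marginal = TRUE, rate = mean(d[[var]]))
      } else {
        fit <- suppressWarnings(stats::glm(fml, data = d,
                                           family = stats::binomial()))
        list(type = type, marginal = FALSE, fit = strip_lm(fit))
      }
    },
    categorical = {
      # conditional class frequencies are sufficient at the small cardinality
      # used here (store labels); fall back to marginal proportions
      list(type = type, marginal = TRUE,
           levels = sort(unique(d[[var]])),
           probs = as.numeric(prop.table(table(d[[var]])[
             sort(unique(d[[var]]))])))
    }
  )
}

# keep prediction ability, drop the heavyweight parts
strip_lm <- function(fit) {
  fit$model <- NULL
  fit$residuals <- NULL
  fit$fitted.values <- NULL
  fit$effects <- NULL
  fit$weights <- NULL
  fit$prior.weights <- NULL
  fit$y <- NULL
  fit$linear.predictors <- NULL
  fit$data <- NULL
  environment(fit$terms) <- baseenv()
  if (!is.null(fit$formula)) environment(fit$formula) <- baseenv()
  fit
}

#' @export
print.synthesis_model <- function(x, ...) {
  cat(sprintf("<synthesis_model> %d variables fitted on %d rows\n",
              length(x$visit_order), x$n_train))
  cat("visit order:", paste(x$visit_order, collapse = " -> "), "\n")
  invisible(x)
}

#' Draw a synthetic table from a fitted synthesizer
#'
#' @param model A `synthesis_model` from [fit_synthesizer()].
#' @param n Number of synthetic rows (default 10000, the standard expansion
#'   size used for the small-cohort analyses).
#' @param rng_seed Integer seed; the same seed reproduces the table exactly.
#' @return A tibble with the synthesized columns in visit order.
#' @export
sample_synthetic <- function(model, n = 10000, rng_seed = 1969) {
  stopifnot(inherits(model, "synthesis_model"))
  if (n < 1) stop("`n` must be at least 1", call. = FALSE)
  with_local_seed(rng_seed, {
    out <- list()
    for (var in model$visit_order) {
      m <- model$models[[var]]
      d <- as.data.frame(out, stringsAsFactors = FALSE)
      draw <- if (isTRUE(m$marginal)) {
        switch(m$type,
          continuous = stats::rnorm(n, m$mean, m$sd),
          binary = stats::rbinom(n, 1, m$rate),
          categorical = sample(m$levels, n, replace = TRUE, prob = m$probs)
        )
      } else {
        switch(m$type,
          continuous = {
            mu <- stats::predict(m$fit, newdata = d)
            stats::rnorm(n, mu, m$sigma)
          },
          binary = {
            pr <- stats::predict(m$fit, newdata = d, type = "response")
            stats::rbinom(n, 1, pr)
          }
        )
      }
      if (isTRUE(m$log_transform)) draw <- pmax(0, expm1(draw))
      if (!is.na(m$gate)) draw <- draw * (out[[m$gate]] == 1)
      out[[var]] <- draw
    }
    tibble::as_tibble(out)
  })
}

#' Fidelity diagnostics between an observed and a synthetic table
#'
#' Continuous variables are compared with the two-sample Kolmogorov-Smirnov
#' test and a quantile-grid mean squared error (mean squared difference of
#' the 1st-99th percentiles of the two samples, a sample-size-independent
#' distance); binary variables are compared by rate difference. The overall
#' MSE averages the variance-standardized quantile MSEs, so it is 0 exactly
#' when every distribution matches and comparable across variable scales.
#'
#' @param observed,synthetic Data frames with identical column sets.
#' @param exclude Columns to skip (identifiers and the like).
#' @return A `fidelity_report` list: `per_variable` tibble (`variable`,
#'   `type`, `ks_statistic`, `ks_p`, `quantile_mse`, `rate_diff`) and
#'   `overall_mse`.
#' @export
fidelity_report <- function(observed, synthetic,
                            exclude = c("session_id", "latent_e")) {
  observed <- as.data.frame(observed)
  synthetic <- as.data.frame(synthetic)
  vars <- setdiff(names(observed), exclude)
  if (!setequal(vars, setdiff(names(synthetic), exclude))) {
    stop("observed and synthetic tables have different schemas", call. = FALSE)
  }
  probs <- seq(0.01, 0.99, by = 0.01)
  rows <- purrr::map_dfr(vars, function(v) {
    xo <- observed[[v]]; xs <- synthetic[[v]]
    type <- column_type(xo)
    if (type == "categorical") {
      lev <- union(unique(xo), unique(xs))
      po <- prop.table(table(factor(xo, lev)))
      ps <- prop.table(table(factor(xs, lev)))
      return(tibble::tibble(variable = v, type = type,
                            ks_statistic = NA_real_, ks_p = NA_real_,
                            quantile_mse = NA_real_,
                            rate_diff = max(abs(po - ps))))
    }
    if (type == "binary") {
      return(tibble::tibble(variable = v, type = type,
                            ks_statistic = NA_real_, ks_p = NA_real_,
                            quantile_mse = NA_real_,
                            rate_diff = mean(xs) - mean(xo)))
    }
    ks <- ks_two_sample(xo, xs)
    qo <- stats::quantile(xo, probs, names = FALSE)
    qs <- stats::quantile(xs, probs, names = FALSE)
    tibble::tibble(variable = v, type = type,
                   ks_statistic = ks$statistic, ks_p = ks$p_value,
                   quantile_mse = mean((qo - qs)^2),
                   rate_diff = NA_real_)
  })
  cont <- rows[rows$type == "continuous", ]
  scaled <- purrr::map2_dbl(cont$variable, cont$quantile_mse, function(v, m) {
    vv <- stats::var(observed[[v]])
    if (vv > 0) m / vv else m
  })
  structure(list(per_variable = rows,
                 overall_mse = if (length(scaled)) mean(scaled) else NA_real_),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report>\n")
  print(as.data.frame(x$per_variable), digits = 4)
  cat(sprintf("overall standardized quantile MSE: %.3g\n", x$overall_mse))
  invisible(x)
}
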