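#' Summarize a sample as (n, mean, sd)
#'
#' @param x Numeric sample with at least 2 values.
#' @return A `group_summary` list with `n`, `mean`, `sd`.
#' @export
group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.list(x) && all(c("n", "mean", "sd") %in% names(x))) {
    x <- structure(x[c("n", "mean", "sd")], class = "group_summary")
  } else {
    x <- as.numeric(x)
    if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
    x <- structure(list(n = length(x), mean = mean(x), sd = stats::sd(x)),
                   class = "group_summary")
  }
  if (x$n < 2) stop("group size must be at least 2", call. = FALSE)
  if (x$sd < 0) stop("sd must be non-negative", call. = FALSE)
  x
}

test_result <- function(statistic, df, p_value, tails, ...) {
  tibble::tibble(statistic = statistic, df = df, p_value = p_value,
                 tails = tails, ...)
}

#' Pooled-variance two-sample Student's t test
#'
#' Works from raw samples or from printed `(n, M, SD)` summary triplets, so
#' published group comparisons can be reconstructed without the underlying
#' data. Uses the pooled (equal-variance) standard error with
#' `df = n_a + n_b - 2` — the classical Student form, which reproduces
#' published t values computed from summary statistics.
#'
#' @param a,b Numeric samples, `group_summary` objects, or lists with
#'   `n`, `mean`, `sd`.
#' @param tails `"two"` (default) or `"one"`; one-tailed p is in the
#'   direction of the observed difference.
#' @return A one-row tibble: `statistic` (t), `df`, `p_value`, `tails`.
#' @export
#' @examples
#' pooled_t_test(list(n = 31, mean = 32.15, sd = 35.37),
#'               list(n = 25, mean = 14.69, sd = 10.93))
pooled_t_test <- function(a, b, tails = c("two", "one")) {
  tails <- match.arg(tails)
  a <- group_summary(a); b <- group_summary(b)
  df <- a$n + b$n - 2
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
  t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  p2 <- 2 * stats::pt(-abs(t), df)
  test_result(t, df, if (tails == "two") p2 else p2 / 2, tails)
}

#' Chi-squared test for two proportions
#'
#' 2x2 chi-squared comparison of success proportions across two groups
#' (df = 1), with optional Yates continuity correction.
#'
#' @param x_a,x_b Success counts.
#' @param n_a,n_b Group sizes.
#' @param yates Apply the continuity correction (default FALSE).
#' @return A one-row tibble with the chi-squared `statistic`, `df`,
#'   `p_value`, and the two proportions.
#' @export
#' @examples
#' two_proportion_chi2(23, 31, 13, 25)
two_proportion_chi2 <- function(x_a, n_a, x_b, n_b, yates = FALSE) {
  counts <- c(x_a, n_a - x_a, x_b, n_b - x_b)
  if (any(counts < 0) || n_a <= 0 || n_b <= 0) {
    stop("invalid counts", call. = FALSE)
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("a marginal of the 2x2 table is zero", call. = FALSE)
  }
  if (x_a / n_a == x_b / n_b) {
    res <- list(statistic = 0, parameter = 1, p.value = 1)
  } else {
    res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  }
  test_result(unname(res$statistic), unname(res$parameter),
              unname(res$p.value), "two",
              prop_a = x_a / n_a, prop_b = x_b / n_b)
}

#' Pearson correlation with t-based inference
#'
#' @param x,y Equal-length numeric samples (n >= 3), non-constant.
#' @param tails `"two"` (default) or `"one"` (in the direction of the
#'   observed sign of r).
#' @return A one-row tibble: `r`, `statistic` (t on n-2 df), `df`,
#'   `p_value`, `tails`.
#' @export
pearson_correlation <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in a sample", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  p2 <- ct$p.value
  test_result(unname(ct$statistic), unname(ct$parameter),
              if (tails == "two") p2 else p2 / 2, tails,
              r = unname(ct$estimate))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Maximum ECDF gap between two samples with the asymptotic p-value; used as
#' the distributional-equivalence check between observed and synthetic data.
#'
#' @param x,y Numeric samples, each with at least 5 values.
#' @return A one-row tibble: `statistic` (D), `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) < 5 || length(y) < 5) {
    stop("need at least 5 observations per sample", call. = FALSE)
  }
  res <- suppressWarnings(stats::ks.test(x, y))
  test_result(unname(res$statistic), NA_real_, unname(res$p.value), "two")
}

#' Run pooled t tests over a table of printed group summaries
#'
#' Batch mode for checking published comparisons mechanically: the input has
#' one row per group with columns `label`, `group`, `n`, `mean`, `sd`; for
#' every `label` the two groups are compared with [pooled_t_test()].
#'
#' @param summaries A data frame as described above (exactly two groups per
#'   label), or a path to such a CSV.
#' @param tails Passed to [pooled_t_test()].
#' @return A tibble with one row per label: group means, t, df, p.
#' @export
batch_summary_tests <- function(summaries, tails = "two") {
  if (is.character(summaries)) {
    summaries <- readr::read_csv(summaries, col_types = readr::cols(
      label = readr::col_character(), group = readr::col_character(),
      .default = readr::col_double()
    ))
  }
  summaries |>
    dplyr::group_by(.data$label) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) != 2) stop("label '", key$label, "' needs exactly 2 groups",
                             call. = FALSE)
      res <- pooled_t_test(list(n = d$n[1], mean = d$mean[1], sd = d$sd[1]),
                           list(n = d$n[2], mean = d$mean[2], sd = d$sd[2]),
                           tails = tails)
      tibble::tibble(
        group_a = d$group[1], mean_a = d$mean[1],
        group_b = d$group[2], mean_b = d$mean[2],
        statistic = res$statistic, df = res$df, p_value = res$p_value
      )
    }) |>
    dplyr::ungroup()
}
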