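#' Procedural-utility objective for the two-store choice problem
#'
#' A shopper allocates income between two stores selling at the same price.
#' Store 1 adds experiential value to the transaction, captured by the
#' multiplier `e` on the log-utility of its consumption bundle: the objective
#' is `e * ln(c1) + ln(c2)`. With `e > 1` the shopping experience itself
#' carries utility (procedural utility) on top of consumption.
#'
#' @param c1,c2 Consumption in stores 1 and 2 (positive).
#' @param e Experiential-value multiplier (non-negative).
#' @return Utility in utils.
#' @export
#' @examples
#' shopper_utility(2, 3, e = 2) # 2*log(2) + log(3)
shopper_utility <- function(c1, c2, e) {
  if (any(c1 <= 0) || any(c2 <= 0)) {
    stop("consumption must be positive for log utility", call. = FALSE)
  }
  if (any(e < 0)) stop("`e` must be non-negative", call. = FALSE)
  e * log(c1) + log(c2)
}

#' Parameters of the two-store choice model
#'
#' @param e Experiential-value multiplier for store 1 (the model motivates
#'   `e > 1`; any non-negative value is accepted for analysis).
#' @param p Common price level in both stores (`p1 = p2 = p > 0`).
#' @param income Budget `M > 0`; credit is excluded, so total spending cannot
#'   exceed `income`.
#' @return A `utility_params` list.
#' @export
utility_params <- function(e, p = 1, income = 100) {
  stopifnot(is.numeric(e), is.numeric(p), is.numeric(income))
  if (e < 0) stop("`e` must be non-negative", call. = FALSE)
  if (p <= 0) stop("`p` must be positive", call. = FALSE)
  if (income <= 0) stop("`income` must be positive", call. = FALSE)
  structure(list(e = e, p = p, income = income), class = "utility_params")
}

#' Closed-form optimal spending split between the two stores
#'
#' Maximizing `e*ln(c1) + ln(c2)` subject to `p*c1 + p*c2 <= M` gives the
#' Cobb-Douglas expenditure share: spending in the experience store is
#' `M*e/(1+e)`, independent of the common price level. A second variant,
#' `M*e/(p+e)`, is also exposed: it replaces the 1 in the denominator with the
#' price and coincides with the share form at `p = 1` (the numeraire used
#' throughout the cohort simulator) but is dimensionally inconsistent away
#' from it, which is why `"derived"` is the default. A numeric grid-search
#' oracle ([numeric_optimum()]) confirms the derived form.
#'
#' @param params A [utility_params()] object.
#' @param variant `"derived"` (default) or `"as_printed"`.
#' @return A list of class `optimum_result`: `spend_store1`, `spend_store2`,
#'   `c1`, `c2`, `formula_variant`, and `corner` (TRUE at the `e = 0` corner
#'   solution where nothing is spent in store 1).
#' @export
#' @examples
#' optimal_spend(utility_params(e = 3, p = 1, income = 100))$spend_store1 # 75
optimal_spend <- function(params, variant = c("derived", "as_printed")) {
  stopifnot(inherits(params, "utility_params"))
  variant <- match.arg(variant)
  e <- params$e; p <- params$p; M <- params$income
  s1 <- switch(variant,
    derived = M * e / (1 + e),
    as_printed = M * e / (p + e)
  )
  s2 <- M - s1
  structure(list(
    spend_store1 = s1,
    spend_store2 = s2,
    c1 = s1 / p,
    c2 = s2 / p,
    formula_variant = variant,
    corner = (e == 0)
  ), class = "optimum_result")
}

#' Grid-search maximization of the choice problem (numeric oracle)
#'
#' Evaluates the utility objective on a uniform grid of store-1 expenditures
#' over the open budget interval and returns the argmax. This is an
#' independent check on the closed form in [optimal_spend()]: the two agree
#' to within one grid step.
#'
#' @param params A [utility_params()] object.
#' @param grid_step Spacing of candidate expenditures, in currency; must be
#'   positive and smaller than `income`.
#' @return An `optimum_result` list (`formula_variant = "numeric"`).
#' @export
numeric_optimum <- function(params, grid_step = params$income / 1e4) {
  stopifnot(inherits(params, "utility_params"))
  if (grid_step <= 0 || grid_step >= params$income) {
    stop("`grid_step` must be in (0, income)", call. = FALSE)
  }
  e <- params$e; p <- params$p; M <- params$income
  s1 <- seq(grid_step, M - grid_step, by = grid_step)
  u <- shopper_utility(s1 / p, (M - s1) / p, e)
  best <- s1[which.max(u)]
  structure(list(
    spend_store1 = best,
    spend_store2 = M - best,
    c1 = best / p,
    c2 = (M - best) / p,
    formula_variant = "numeric",
    corner = FALSE
  ), class = "optimum_result")
}

#' Dwell time implied by experiential value
#'
#' The model links neurologic value to behavior by assuming the value of the
#' shopping experience is proportional to time spent in the store:
#' `dwell = kappa * e` minutes, with `kappa` the minutes of dwell per unit of
#' experiential value. A shopper who derives little neurologic value leaves
#' sooner.
#'
#' @param e Experiential-value multiplier (vectorized).
#' @param kappa Minutes of dwell per unit `e` (positive).
#' @return Predicted dwell time in minutes.
#' @export
predicted_dwell <- function(e, kappa = 10) {
  if (any(e < 0)) stop("`e` must be non-negative", call. = FALSE)
  if (kappa <= 0) stop("`kappa` must be positive", call. = FALSE)
  kappa * e
}
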