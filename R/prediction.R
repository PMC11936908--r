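#' Discretize purchase amounts into a purchase-incidence label
#'
#' @param table Data frame with a `purchase_usd` column (non-negative).
#' @return The table with an added integer `purchased` column
#'   (`purchase_usd > 0`).
#' @export
discretize_purchase <- function(table) {
  if (!"purchase_usd" %in% names(table)) {
    stop("column `purchase_usd` not found", call. = FALSE)
  }
  if (any(table$purchase_usd < 0)) {
    stop("negative purchase amounts are invalid", call. = FALSE)
  }
  table$purchased <- as.integer(table$purchase_usd > 0)
  table
}

#' Classification performance metrics
#'
#' Sensitivity (true-positive rate), specificity (true-negative rate),
#' accuracy at the decision threshold, AUC as the rank (Mann-Whitney)
#' statistic with ties counted half, and MSE of the predicted probabilities
#' against the 0/1 labels (the Brier score).
#'
#' @param labels Binary vector (0/1).
#' @param probabilities Predicted probabilities of the positive class.
#' @param threshold Decision threshold (default 0.5).
#' @return A named list: `sensitivity`, `specificity`, `accuracy`, `auc`,
#'   `mse`, and the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
#' @examples
#' classification_metrics(c(1, 1, 0, 0), c(0.9, 0.6, 0.4, 0.1))
classification_metrics <- function(labels, probabilities, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) != length(probabilities)) {
    stop("labels and probabilities differ in length", call. = FALSE)
  }
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: only one class present", call. = FALSE)
  }
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  r <- rank(probabilities)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(labels),
    auc = auc,
    mse = mean((probabilities - labels)^2),
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Specification of the ensemble purchase classifier
#'
#' @param features Feature columns; defaults to the neurophysiologic and
#'   behavioral predictors plus the two control flags.
#' @param label Binary label column (default `purchased`).
#' @param learners Subset of `"random_forest"`, `"gradient_boosting"`,
#'   `"extra_trees"` (three heterogeneous tree learners whose predicted
#'   probabilities are averaged without weights).
#' @param hyperparameter_grid Per-learner named list of candidate values;
#'   every combination is evaluated by inner cross-validated accuracy.
#' @param n_folds Outer stratified folds (default 5).
#' @param inner_folds Folds of the inner tuning loop (default 3).
#' @param decision_threshold Probability threshold for class assignment.
#' @param mode `"cv"` (stratified k-fold on the full table, default) or
#'   `"holdout"` (a stratified 50/50 train/test split).
#' @param rng_seed Seed controlling folds and learner randomness.
#' @return A `prediction_spec` list.
#' @export
prediction_spec <- function(features = c("peak_immersion", "dwell_min",
                                         "loyal", "companion"),
                            label = "purchased",
                            learners = c("random_forest", "gradient_boosting",
                                         "extra_trees"),
                            hyperparameter_grid = default_hyperparameter_grid(),
                            n_folds = 5,
                            inner_folds = 3,
                            decision_threshold = 0.5,
                            mode = c("cv", "holdout"),
                            rng_seed = 1969) {
  mode <- match.arg(mode)
  known <- c("random_forest", "gradient_boosting", "extra_trees")
  if (!all(learners %in% known)) {
    stop("unknown learner(s): ", paste(setdiff(learners, known), collapse = ", "),
         call. = FALSE)
  }
  if (n_folds < 2) stop("`n_folds` must be at least 2", call. = FALSE)
  if (decision_threshold <= 0 || decision_threshold >= 1) {
    stop("`decision_threshold` must lie in (0, 1)", call. = FALSE)
  }
  structure(list(features = features, label = label, learners = learners,
                 hyperparameter_grid = hyperparameter_grid,
                 n_folds = n_folds, inner_folds = inner_folds,
                 decision_threshold = decision_threshold,
                 mode = mode, rng_seed = rng_seed),
            class = "prediction_spec")
}

#' Default hyperparameter search grid for the three tree learners
#'
#' @return A named list of per-learner candidate grids.
#' @export
default_hyperparameter_grid <- function() {
  # candidates lean toward strong smoothing: with a handful of behavioral
  # features and a noisy label, deep trees overfit and dilute the ensemble
  list(
    random_forest = list(ntree = 300, nodesize = c(25, 75)),
    gradient_boosting = list(eta = 0.05, max_depth = c(1, 2), nrounds = 200),
    extra_trees = list(num.trees = 300, min.node.size = c(40, 100))
  )
}

make_stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

fit_one_learner <- function(learner, params, x, y, seed) {
  set.seed(seed)
  switch(learner,
    random_forest = {
      fit <- randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        ntree = params$ntree %||% 300,
        mtry = params$mtry %||% max(1, floor(sqrt(ncol(x)))),
        nodesize = params$nodesize %||% 1
      )
      list(learner = learner, fit = fit)
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = y)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      eta = params$eta %||% 0.3,
                      max_depth = params$max_depth %||% 4,
                      nthread = 1),
        data = dtrain,
        nrounds = params$nrounds %||% 100,
        verbose = 0
      )
      list(learner = learner, fit = fit)
    },
    extra_trees = {
      d <- data.frame(x, .y = factor(y, levels = c(0, 1)))
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = d,
        probability = TRUE, splitrule = "extratrees",
        num.trees = params$num.trees %||% 300,
        min.node.size = params$min.node.size %||% 10,
        num.threads = 1, seed = seed
      )
      list(learner = learner, fit = fit)
    }
  )
}

predict_one_learner <- function(model, x) {
  switch(model$learner,
    random_forest = unname(
      stats::predict(model$fit, newdata = x, type = "prob")[, "1"]
    ),
    gradient_boosting = as.numeric(
      stats::predict(model$fit, newdata = xgboost::xgb.DMatrix(as.matrix(x)))
    ),
    extra_trees = unname(
      stats::predict(model$fit, data = data.frame(x),
                     num.threads = 1)$predictions[, "1"]
    )
  )
}

expand_param_grid <- function(grid) {
  if (length(grid) == 0) return(list(list()))
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) as.list(combos[i, , drop = FALSE]))
}

tune_learner <- function(learner, grid, x, y, inner_folds, threshold, seed) {
  candidates <- expand_param_grid(grid)
  if (length(candidates) == 1) return(candidates[[1]])
  fold <- make_stratified_folds(y, inner_folds)
  acc <- vapply(candidates, function(params) {
    correct <- 0
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      m <- fit_one_learner(learner, params, x[tr, , drop = FALSE], y[tr],
                           seed = seed + f)
      pr <- predict_one_learner(m, x[!tr, , drop = FALSE])
      correct <- correct + sum((pr >= threshold) == (y[!tr] == 1))
    }
    correct / length(y)
  }, numeric(1))
  candidates[[which.max(acc)]]
}

#' Grid-searched, cross-validated ensemble purchase classification
#'
#' For each learner an exhaustive grid search selects hyperparameters by
#' inner cross-validated accuracy on the training part; the ensemble
#' prediction is the unweighted mean of the learners' predicted
#' probabilities. Performance is reported out-of-sample: either outer
#' stratified k-fold cross-validation (default) or a stratified 50/50
#' holdout. A logistic-regression baseline on the same features is always
#' included. Pooled metrics aggregate the out-of-fold confusion counts and
#' predictions, not fold averages.
#'
#' @param table Labeled data frame (see [discretize_purchase()]).
#' @param spec A [prediction_spec()].
#' @return A `prediction_report` list: `pooled` (ensemble metrics), `per_fold`
#'   tibble, `baseline` (logistic metrics), `per_learner_pooled`,
#'   `selected_hyperparameters`, `predictions` (out-of-fold tibble), `spec`.
#' @export
tune_and_evaluate <- function(table, spec = prediction_spec()) {
  stopifnot(inherits(spec, "prediction_spec"))
  d <- as.data.frame(table)
  needed <- c(spec$features, spec$label)
  missing_cols <- setdiff(needed, names(d))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  y <- as.integer(d[[spec$label]])
  if (length(unique(y)) < 2) {
    stop("both classes must be present in the label", call. = FALSE)
  }
  if (nrow(d) < 10 * spec$n_folds) {
    stop("need at least ", 10 * spec$n_folds, " rows", call. = FALSE)
  }
  x <- d[, spec$features, drop = FALSE]
  x[] <- lapply(x, as.numeric)

  with_local_seed(spec$rng_seed, {
    if (spec$mode == "holdout") {
      fold <- make_stratified_folds(y, 2)
      outer_folds <- 1L  # evaluate on the held-out half only
    } else {
      fold <- make_stratified_folds(y, spec$n_folds)
      outer_folds <- seq_len(spec$n_folds)
    }
    oof <- vector("list", length(outer_folds))
    selected <- list()
    for (f in outer_folds) {
      tr <- fold != f
      xt <- x[tr, , drop = FALSE]; yt <- y[tr]
      probs <- matrix(NA_real_, nrow = sum(!tr), ncol = length(spec$learners),
                      dimnames = list(NULL, spec$learners))
      for (ln in spec$learners) {
        best <- tune_learner(ln, spec$hyperparameter_grid[[ln]], xt, yt,
                             spec$inner_folds, spec$decision_threshold,
                             seed = spec$rng_seed + 97 * f)
        selected[[ln]][[length(selected[[ln]]) + 1]] <- best
        m <- fit_one_learner(ln, best, xt, yt, seed = spec$rng_seed + 13 * f)
        probs[, ln] <- predict_one_learner(m, x[!tr, , drop = FALSE])
      }
      base_fit <- suppressWarnings(stats::glm.fit(
        cbind(1, as.matrix(xt)), yt, family = stats::binomial()
      ))
      base_prob <- as.numeric(
        stats::plogis(cbind(1, as.matrix(x[!tr, , drop = FALSE])) %*%
                        base_fit$coefficients)
      )
      oof[[match(f, outer_folds)]] <- tibble::tibble(
        row = which(!tr), fold = f, label = y[!tr],
        ensemble_prob = rowMeans(probs),
        baseline_prob = base_prob,
        tibble::as_tibble(probs, .name_repair = "minimal")
      )
    }
    oof <- dplyr::bind_rows(oof)
    thr <- spec$decision_threshold
    per_fold <- oof |>
      dplyr::group_by(.data$fold) |>
      dplyr::group_modify(function(g, key) {
        tibble::as_tibble(classification_metrics(g$label, g$ensemble_prob, thr))
      }) |>
      dplyr::ungroup()
    per_learner <- purrr::map(
      stats::setNames(spec$learners, spec$learners),
      function(ln) classification_metrics(oof$label, oof[[ln]], thr)
    )
    structure(list(
      pooled = classification_metrics(oof$label, oof$ensemble_prob, thr),
      per_fold = per_fold,
      baseline = classification_metrics(oof$label, oof$baseline_prob, thr),
      per_learner_pooled = per_learner,
      selected_hyperparameters = selected,
      predictions = oof,
      spec = spec
    ), class = "prediction_report")
  })
}

#' @export
print.prediction_report <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<prediction_report> %s, %d out-of-sample predictions\n",
    if (x$spec$mode == "cv") sprintf("%d-fold CV", x$spec$n_folds)
    else "50/50 holdout",
    nrow(x$predictions)
  ))
  cat(sprintf(
    "  ensemble: sens %.3f  spec %.3f  acc %.3f  AUC %.3f  MSE %.4f\n",
    p$sensitivity, p$specificity, p$accuracy, p$auc, p$mse
  ))
  b <- x$baseline
  cat(sprintf(
    "  logistic baseline: sens %.3f  spec %.3f  acc %.3f  AUC %.3f\n",
    b$sensitivity, b$specificity, b$accuracy, b$auc
  ))
  invisible(x)
}

#' Serialize a prediction report as JSON
#'
#' @param report A `prediction_report`.
#' @param path Output path.
#' @param include_predictions Write the per-row out-of-fold predictions too.
#' @return `path`, invisibly.
#' @export
write_prediction_json <- function(report, path, include_predictions = FALSE) {
  out <- list(
    pooled = report$pooled,
    per_fold = report$per_fold,
    baseline = report$baseline,
    per_learner_pooled = report$per_learner_pooled,
    selected_hyperparameters = report$selected_hyperparameters,
    spec = unclass(report$spec)
  )
  if (include_predictions) out$predictions <- report$predictions
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
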