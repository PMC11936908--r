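#' Configuration of a full analysis pipeline run
#'
#' @param output_dir Directory for all stage artifacts (created if absent).
#' @param seed Global seed; each stage derives its own child seed from it by
#'   a fixed scheme (see [stage_seed()]), so stages can be rerun in
#'   isolation.
#' @param profiles Store simulation profiles ([default_store_profiles()]).
#' @param n_synthetic Synthetic rows per store (default 10000; must be at
#'   least the observed per-store count).
#' @param visit_order Synthesis visit order over the analysis columns;
#'   `NULL` uses the causal default (demographics, then Immersion metrics,
#'   then dwell, then purchase incidence and amount).
#' @param mediation Covariate/bootstrap settings for the mediation stage, as
#'   a list (`covariates`, `bootstrap_reps`, `standardize`).
#' @param prediction A [prediction_spec()] for the prediction stage.
#' @param stages Which stages to run, in pipeline order. Disabling
#'   `"synthesize"` makes mediation and prediction run on the small observed
#'   cohort instead of the synthetic expansion.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            seed = 1969,
                            profiles = default_store_profiles(),
                            n_synthetic = 10000,
                            visit_order = NULL,
                            mediation = list(covariates = character(),
                                             bootstrap_reps = 2000,
                                             standardize = FALSE),
                            prediction = prediction_spec(),
                            stages = c("simulate", "metrics", "synthesize",
                                       "stats", "mediate", "predict")) {
  n_obs <- sum(purrr::map_dbl(profiles, "n_sessions"))
  if (n_synthetic < n_obs) {
    stop("`n_synthetic` must be at least the observed cohort size",
         call. = FALSE)
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 profiles = profiles, n_synthetic = n_synthetic,
                 visit_order = visit_order, mediation = mediation,
                 prediction = prediction, stages = stages),
            class = "pipeline_config")
}

pipeline_stage_registry <- c("simulate", "metrics", "synthesize", "stats",
                             "mediate", "predict")

#' Deterministic child seed for a pipeline stage
#'
#' `child = (seed * 131 + 1000 * stage_index) mod (2^31 - 1)`, with the stage
#' index taken from the fixed stage registry. The scheme is documented so a
#' single stage can be rerun in isolation with exactly the stream it had in
#' the full run.
#'
#' @param seed Global pipeline seed.
#' @param stage Stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(seed, stage) {
  idx <- match(stage, pipeline_stage_registry)
  if (is.na(idx)) stop("unknown stage '", stage, "'", call. = FALSE)
  as.integer((as.numeric(seed) * 131 + 1000 * idx) %% (2^31 - 1))
}

default_visit_order <- function() {
  c("age", "female", "loyal", "companion", "avg_immersion", "peak_immersion",
    "dwell_min", "purchased", "purchase_usd")
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

run_stage <- function(stage, input_desc, code) {
  t0 <- Sys.time()
  res <- tryCatch(code, error = function(e) {
    stop(sprintf("stage '%s' failed on %s: %s", stage, input_desc,
                 conditionMessage(e)), call. = FALSE)
  })
  list(result = res,
       elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
}

#' Run the full simulate / measure / synthesize / test / mediate / predict
#' pipeline
#'
#' Executes the enabled stages in order, each stage reading the previous
#' stage's CSV/JSON artifacts from the output directory, and writes a run
#' manifest. The run is fully reproducible from (config, seed).
#'
#' Artifacts: `sessions.csv`, `traces.csv`, `metrics.csv`, `synthetic.csv`,
#' `fidelity.json`, `tests.csv`, `mediation_<store>.json`,
#' `prediction_report.json`, `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$output_dir, f)
  timings <- list()
  inventory <- character()
  store_labels <- purrr::map_chr(config$profiles, "store_label")

  if ("simulate" %in% config$stages) {
    st <- run_stage("simulate", "store profiles", {
      cohort <- generate_cohort(config$profiles,
                                rng_seed = stage_seed(config$seed, "simulate"))
      write_sessions(cohort$sessions, out("sessions.csv"))
      write_immersion_traces(cohort$traces, out("traces.csv"))
      pipeline_log("simulate", "%d sessions, %d traces, purchase frequency %.2f",
                   nrow(cohort$sessions), length(cohort$traces),
                   mean(cohort$sessions$purchase_usd > 0))
      cohort
    })
    timings$simulate <- st$elapsed_sec
    inventory <- c(inventory, "sessions.csv", "traces.csv")
  }

  if ("metrics" %in% config$stages) {
    st <- run_stage("metrics", out("traces.csv"), {
      traces <- read_immersion_traces(out("traces.csv"))
      metrics <- session_metrics_table(traces)
      write_session_metrics(metrics, out("metrics.csv"))
      pipeline_log("metrics", "%d sessions, mean peak Immersion %.3f",
                   nrow(metrics), mean(metrics$peak_immersion))
      metrics
    })
    timings$metrics <- st$elapsed_sec
    inventory <- c(inventory, "metrics.csv")
  }

  sessions <- read_sessions(out("sessions.csv"))
  metrics <- readr::read_csv(out("metrics.csv"), col_types = readr::cols(
    session_id = readr::col_character(), .default = readr::col_double()
  ))
  observed <- sessions |>
    dplyr::inner_join(metrics[, c("session_id", "avg_immersion",
                                  "peak_immersion")], by = "session_id") |>
    discretize_purchase()

  analysis_table <- observed
  if ("synthesize" %in% config$stages) {
    st <- run_stage("synthesize", out("sessions.csv"), {
      vo <- config$visit_order %||% default_visit_order()
      syn <- purrr::map(store_labels, function(s) {
        obs_s <- observed[observed$store == s,
                          c("store", vo), drop = FALSE]
        model <- fit_synthesizer(obs_s[, vo, drop = FALSE], visit_order = vo)
        tab <- sample_synthetic(model, n = config$n_synthetic,
                                rng_seed = stage_seed(config$seed, "synthesize") +
                                  match(s, store_labels))
        tab$store <- s
        tab$purchased <- as.integer(tab$purchased)
        tab
      })
      syn <- dplyr::bind_rows(syn)
      readr::write_csv(syn, out("synthetic.csv"))
      fid <- purrr::map(stats::setNames(store_labels, store_labels), function(s) {
        rep <- fidelity_report(observed[observed$store == s, , drop = FALSE],
                               syn[syn$store == s, , drop = FALSE],
                               exclude = c("session_id", "latent_e", "store"))
        list(per_variable = rep$per_variable, overall_mse = rep$overall_mse)
      })
      jsonlite::write_json(fid, out("fidelity.json"), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      pipeline_log("synthesize", "%d synthetic rows/store; overall MSE %s",
                   config$n_synthetic,
                   paste(sprintf("%s=%.3g", store_labels,
                                 purrr::map_dbl(fid, "overall_mse")),
                         collapse = ", "))
      syn
    })
    timings$synthesize <- st$elapsed_sec
    inventory <- c(inventory, "synthetic.csv", "fidelity.json")
    analysis_table <- st$result
  }

  if ("stats" %in% config$stages) {
    st <- run_stage("stats", out("sessions.csv"), {
      tests <- cohort_test_battery(observed,
                                   store_a = store_labels[1],
                                   store_b = store_labels[2])
      readr::write_csv(tests, out("tests.csv"))
      pipeline_log("stats", "%d test rows", nrow(tests))
      tests
    })
    timings$stats <- st$elapsed_sec
    inventory <- c(inventory, "tests.csv")
  }

  if ("mediate" %in% config$stages) {
    st <- run_stage("mediate", "analysis table", {
      for (s in store_labels) {
        d <- analysis_table[analysis_table$store == s, , drop = FALSE]
        if (nrow(d) < 100) {
          pipeline_log("mediate",
                       "store %s: n = %d is small; mediation is low-powered and may fail to reach significance",
                       s, nrow(d))
        }
        res <- fit_mediation(d, mediation_spec(
          covariates = config$mediation$covariates %||% character(),
          standardize = isTRUE(config$mediation$standardize),
          bootstrap_reps = config$mediation$bootstrap_reps %||% 2000,
          rng_seed = stage_seed(config$seed, "mediate") +
            match(s, store_labels)
        ))
        write_mediation_json(res, out(sprintf("mediation_%s.json", s)))
        pipeline_log("mediate", "store %s: indirect %.4g, Sobel p %.3g",
                     s, res$indirect, res$sobel$p_value)
      }
      TRUE
    })
    timings$mediate <- st$elapsed_sec
    inventory <- c(inventory,
                   sprintf("mediation_%s.json", store_labels))
  }

  if ("predict" %in% config$stages) {
    st <- run_stage("predict", "analysis table", {
      spec <- config$prediction
      spec$rng_seed <- stage_seed(config$seed, "predict")
      report <- tune_and_evaluate(analysis_table, spec)
      write_prediction_json(report, out("prediction_report.json"))
      pipeline_log("predict", "pooled accuracy %.3f, AUC %.3f",
                   report$pooled$accuracy, report$pooled$auc)
      report
    })
    timings$predict <- st$elapsed_sec
    inventory <- c(inventory, "prediction_report.json")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("immersr")),
    seed = config$seed,
    config_hash = digest::digest(config[setdiff(names(config), "output_dir")]),
    stages = config$stages,
    stage_timings_sec = timings,
    files = inventory
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  missing_files <- inventory[!file.exists(file.path(config$output_dir, inventory))]
  if (length(missing_files)) {
    stop("manifest lists missing artifacts: ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  invisible(manifest)
}

#' Store-comparison test battery on an observed cohort
#'
#' Reproduces the standard between-store comparisons: pooled t tests on
#' dwell time, purchase amount, average Immersion and Peak Immersion, and
#' chi-squared tests on purchase frequency and the return-customer rate.
#'
#' @param observed Joined sessions + metrics table with a `store` column.
#' @param store_a,store_b The two store labels to compare.
#' @return A tibble with one row per comparison.
#' @export
cohort_test_battery <- function(observed, store_a = "WS", store_b = "MS") {
  a <- observed[observed$store == store_a, ]
  b <- observed[observed$store == store_b, ]
  t_vars <- c(dwell_min = "dwell_min", purchase_usd = "purchase_usd",
              avg_immersion = "avg_immersion", peak_immersion = "peak_immersion")
  t_rows <- purrr::imap_dfr(t_vars, function(v, nm) {
    res <- pooled_t_test(a[[v]], b[[v]])
    tibble::tibble(label = nm, test = "pooled_t",
                   mean_a = mean(a[[v]]), mean_b = mean(b[[v]]),
                   statistic = res$statistic, df = res$df,
                   p_value = res$p_value)
  })
  chi_rows <- purrr::imap_dfr(
    list(purchase_frequency = "purchased", return_customers = "loyal"),
    function(v, nm) {
      res <- two_proportion_chi2(sum(a[[v]]), nrow(a), sum(b[[v]]), nrow(b))
      tibble::tibble(label = nm, test = "chi2",
                     mean_a = mean(a[[v]]), mean_b = mean(b[[v]]),
                     statistic = res$statistic, df = res$df,
                     p_value = res$p_value)
    }
  )
  dplyr::bind_rows(t_rows, chi_rows)
}

#' Human-readable summary of a pipeline run
#'
#' @param output_dir The pipeline output directory (containing
#'   `manifest.json`).
#' @return A character vector of markdown lines, invisibly; also printed.
#' @export
summarize_results <- function(output_dir) {
  mf_path <- file.path(output_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("no manifest.json in ", output_dir,
                                  call. = FALSE)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  missing_files <- manifest$files[!file.exists(file.path(output_dir,
                                                         manifest$files))]
  if (length(missing_files)) {
    stop("missing artifacts: ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  lines <- c(
    "# Pipeline run summary",
    sprintf("- seed: %s | config hash: %s | package %s",
            manifest$seed, manifest$config_hash, manifest$package_version),
    ""
  )
  tests_path <- file.path(output_dir, "tests.csv")
  if (file.exists(tests_path)) {
    tests <- readr::read_csv(tests_path, col_types = readr::cols())
    lines <- c(lines, "## Between-store comparisons", "",
               "| comparison | test | mean A | mean B | statistic | p |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %s | %.3f | %.3f | %.3f | %.4f |",
                       tests$label, tests$test, tests$mean_a, tests$mean_b,
                       tests$statistic, tests$p_value),
               "")
  }
  med_files <- grep("^mediation_", manifest$files, value = TRUE)
  for (f in med_files) {
    m <- jsonlite::read_json(file.path(output_dir, f), simplifyVector = TRUE)
    lines <- c(lines, sprintf(
      "## Mediation (%s): a = %.4g (p %.3g), b = %.4g (p %.3g), direct = %.4g, indirect = %.4g [%.4g, %.4g]",
      sub("^mediation_(.*)\\.json$", "\\1", f),
      m$a_path, m$a_p, m$b_path, m$b_p, m$c_prime, m$indirect,
      m$indirect_ci[1], m$indirect_ci[2]
    ))
  }
  pred_path <- file.path(output_dir, "prediction_report.json")
  if (file.exists(pred_path)) {
    p <- jsonlite::read_json(pred_path, simplifyVector = TRUE)$pooled
    lines <- c(lines, "", sprintf(
      "## Purchase prediction (ensemble, pooled): sensitivity %.3f, specificity %.3f, accuracy %.3f, AUC %.3f, MSE %.4f",
      p$sensitivity, p$specificity, p$accuracy, p$auc, p$mse
    ))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
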