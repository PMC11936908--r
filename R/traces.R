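#' Construct a validated 1 Hz Immersion trace
#'
#' An Immersion trace is the 1 Hz neurophysiologic Immersion series recorded
#' from a sales associate over one service encounter, from the greeting
#' (`t = 0`) to the customer's departure. Values are on the measurement
#' platform's arbitrary positive scale (session means are typically around
#' 4.4 units).
#'
#' Short dropouts are tolerated: gaps of at most `max_gap_sec` seconds between
#' consecutive samples are forward-filled with the last observed value before
#' validation. A longer gap marks the session invalid.
#'
#' @param session_id Identifier for the encounter (coerced to character).
#' @param times Integer-valued sample times in seconds since the greeting,
#'   strictly increasing, nominally starting at 0.
#' @param values Positive, finite Immersion values, one per time point.
#' @param max_gap_sec Largest tolerated sampling gap in seconds; gaps up to
#'   this size are forward-filled, larger ones are an error. Default 5.
#'
#' @return An object of class `immersion_trace`: a list with elements
#'   `session_id`, `times` and `values` on a regular 1 Hz grid.
#' @export
#' @examples
#' tr <- immersion_trace("s1", 0:11, 4 + sin(0:11))
#' peak_immersion(tr)
immersion_trace <- function(session_id, times, values, max_gap_sec = 5) {
  session_id <- as.character(session_id)[1]
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(values) || any(!is.finite(values))) {
    stop("trace '", session_id, "' contains missing or non-finite samples",
         call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("trace '", session_id, "' has non-increasing sample times",
         call. = FALSE)
  }
  if (any(values <= 0)) {
    stop("trace '", session_id, "' has non-positive Immersion values",
         call. = FALSE)
  }
  filled <- fill_trace_gaps(times, values, max_gap_sec = max_gap_sec,
                            session_id = session_id)
  structure(
    list(session_id = session_id, times = filled$times, values = filled$values),
    class = "immersion_trace"
  )
}

#' @export
print.immersion_trace <- function(x, ...) {
  cat(sprintf(
    "<immersion_trace> session %s: %d samples over %.0f s, mean %.3f\n",
    x$session_id, length(x$values), max(x$times) - min(x$times),
    mean(x$values)
  ))
  invisible(x)
}

# Regularize a nominally 1 Hz series: forward-fill missing seconds when the
# gap is short, fail the session when it is not.
fill_trace_gaps <- function(times, values, max_gap_sec = 5, session_id = "?") {
  gaps <- diff(times)
  if (any(gaps > max_gap_sec + 1)) {
    stop("trace '", session_id, "' has a sampling gap longer than ",
         max_gap_sec, " s; session is invalid", call. = FALSE)
  }
  grid <- seq(times[1], times[length(times)])
  idx <- findInterval(grid, times)
  list(times = grid, values = values[idx])
}

assert_trace <- function(trace, min_samples = 10) {
  if (!inherits(trace, "immersion_trace")) {
    stop("expected an `immersion_trace` object", call. = FALSE)
  }
  if (length(trace$values) < min_samples) {
    stop("trace '", trace$session_id, "' has fewer than ", min_samples,
         " samples; too short for stable session metrics", call. = FALSE)
  }
  invisible(trace)
}

#' Read Immersion traces from a long-format CSV file
#'
#' The file must have the header `session_id,t_sec,immersion`, with integer
#' seconds and one row per 1 Hz sample; one file may hold many sessions.
#'
#' @param path Path to the CSV file.
#' @param max_gap_sec Forward-fill tolerance passed to [immersion_trace()].
#' @return A named list of `immersion_trace` objects, one per session.
#' @export
read_immersion_traces <- function(path, max_gap_sec = 5) {
  df <- readr::read_csv(path, col_types = readr::cols(
    session_id = readr::col_character(),
    t_sec = readr::col_double(),
    immersion = readr::col_double()
  ))
  split(df, df$session_id) |>
    purrr::map(function(d) {
      d <- d[order(d$t_sec), ]
      immersion_trace(d$session_id[1], d$t_sec, d$immersion,
                      max_gap_sec = max_gap_sec)
    })
}

#' Write Immersion traces to the long CSV dialect
#'
#' @param traces A list of `immersion_trace` objects.
#' @param path Output CSV path (header `session_id,t_sec,immersion`).
#' @return `path`, invisibly.
#' @export
write_immersion_traces <- function(traces, path) {
  df <- purrr::map_dfr(traces, function(tr) {
    tibble::tibble(session_id = tr$session_id, t_sec = tr$times,
                   immersion = tr$values)
  })
  readr::write_csv(df, path)
  invisible(path)
}
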