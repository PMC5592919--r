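#' Pooled population sleep metrics (FPS, BF, MSBD)
#'
#' Computes the three population sleep metrics used to screen lines by
#' multi-worm tracker recordings:
#' \itemize{
#'   \item FPS, fractional population sleep: total time in sleep bouts for
#'     all animals divided by total time tracked for all animals;
#'   \item BF, bout frequency: number of sleep bouts (>= `min_bout`) for all
#'     animals divided by total time tracked, in bouts per second;
#'   \item MSBD, mean sleep bout duration: FPS / BF, equal to total sleep
#'     time divided by bout count, in seconds.
#' }
#' Metrics are pooled ratios of sums across animals, not averages of
#' per-animal fractions, so animals tracked longer weigh more. Animals with
#' zero tracked time are excluded and do not affect the result.
#'
#' @param traces A list of [velocity_trace()] objects (a single trace is
#'   also accepted).
#' @param min_bout Minimum sleep-bout span in seconds (default 10).
#' @param eps Motionless velocity threshold in mm/sec (default 1e-3).
#' @return A one-row data.frame with columns `fps`, `bf` (per second),
#'   `msbd` (seconds, `NA` when there are no bouts), `n_animals`,
#'   `total_tracked` (s), `total_sleep` (s), `n_bouts`.
#' @examples
#' still <- velocity_trace(rep(0, 300), dt = 1, animal_id = "still")
#' mover <- velocity_trace(rep(0.2, 300), dt = 1, animal_id = "mover")
#' population_metrics(list(still, mover))  # fps 0.5, bf 1/600, msbd 300
#' @export
population_metrics <- function(traces, min_bout = 10, eps = 1e-3) {
  if (inherits(traces, "velocity_trace")) traces <- list(traces)
  if (!length(traces) || !all(vapply(traces, inherits, TRUE, "velocity_trace"))) {
    stop_input("`traces` must be one or more velocity_trace objects")
  }
  tracked <- vapply(traces, tracked_time, 0)
  traces <- traces[tracked > 0]
  total_tracked <- sum(tracked)
  if (total_tracked <= 0) {
    stop_input("total tracked time is zero; population metrics undefined")
  }
  sleep <- 0
  n_bouts <- 0L
  for (tr in traces) {
    b <- detect_sleep_bouts(tr, min_bout = min_bout, eps = eps)
    sleep <- sleep + sum(b$duration)
    n_bouts <- n_bouts + nrow(b)
  }
  fps <- sleep / total_tracked
  bf <- n_bouts / total_tracked
  data.frame(
    fps = fps, bf = bf,
    msbd = if (n_bouts > 0) sleep / n_bouts else NA_real_,
    n_animals = length(traces), total_tracked = total_tracked,
    total_sleep = sleep, n_bouts = n_bouts
  )
}

#' Restrict a velocity trace to a sampling window
#'
#' Returns the sub-trace whose sample times fall in `[start, start + length)`
#' — the 10-min population sampling window of the tracker assay. The window
#' is truncated to the trace extent; the tracked mask is preserved.
#'
#' @param trace A [velocity_trace()].
#' @param start Window start in seconds (absolute time, same origin as
#'   `trace$t0`).
#' @param length Window length in seconds (default 600 = 10 min).
#' @return A [velocity_trace()] covering the overlap.
#' @export
sample_window <- function(trace, start, length = 600) {
  stopifnot(inherits(trace, "velocity_trace"))
  check_scalar(start, "start")
  check_scalar(length, "length", lower = 0, strict_lower = TRUE)
  times <- trace$t0 + (seq_along(trace$velocity) - 1L) * trace$dt
  keep <- times >= start & times < start + length
  if (!any(keep)) {
    stop_input("sampling window does not overlap the trace")
  }
  velocity_trace(trace$velocity[keep], dt = trace$dt, t0 = min(times[keep]),
                 animal_id = trace$animal_id, tracked = trace$tracked[keep])
}
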