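#' Construct a velocity trace for one animal
#'
#' A velocity trace is the substrate for sleep-bout detection: one animal's
#' speed (mm/sec) sampled at a fixed interval by a tracker. An optional
#' tracked mask marks samples where the tracker actually followed the animal;
#' untracked samples contribute to neither sleep nor motion time.
#'
#' @param velocity Numeric vector of speeds in mm/sec, length >= 1. Must be
#'   non-negative wherever `tracked` is `TRUE`.
#' @param dt Sampling interval in seconds (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param animal_id Identifier for the animal (single string).
#' @param tracked Optional logical vector, one entry per sample; `TRUE` means
#'   the animal was tracked at that sample. Defaults to all tracked.
#'
#' @return An object of class `velocity_trace`: a list with fields
#'   `animal_id`, `t0`, `dt`, `velocity`, `tracked`.
#' @examples
#' tr <- velocity_trace(c(0, 0, 0.2, 0.1), dt = 1)
#' tracked_time(tr)
#' @export
velocity_trace <- function(velocity, dt, t0 = 0, animal_id = "animal",
                           tracked = NULL) {
  if (length(velocity) < 1L || !is.numeric(velocity)) {
    stop_input("velocity trace must contain at least one numeric sample")
  }
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar(t0, "t0")
  if (is.null(tracked)) tracked <- rep(TRUE, length(velocity))
  if (!is.logical(tracked) || length(tracked) != length(velocity)) {
    stop_input("`tracked` must be a logical vector matching `velocity`")
  }
  tracked <- tracked & !is.na(velocity)
  if (any(velocity[tracked] < 0)) {
    stop_input("tracked velocities must be non-negative")
  }
  structure(
    list(animal_id = as.character(animal_id)[1L], t0 = t0, dt = dt,
         velocity = as.numeric(velocity), tracked = tracked),
    class = "velocity_trace"
  )
}

#' @export
print.velocity_trace <- function(x, ...) {
  cat(sprintf(
    "<velocity_trace> %s: %d samples @ dt = %g s (%.1f s tracked of %.1f s)\n",
    x$animal_id, length(x$velocity), x$dt, tracked_time(x),
    length(x$velocity) * x$dt))
  invisible(x)
}

#' Total tracked time of a velocity trace
#'
#' @param trace A [velocity_trace()].
#' @return Tracked time in seconds: number of tracked samples times `dt`.
#' @export
tracked_time <- function(trace) {
  stopifnot(inherits(trace, "velocity_trace"))
  sum(trace$tracked) * trace$dt
}

# Shared run-length kernel: maximal runs of TRUE in `flag` whose span
# (run length * dt) is >= min_bout, reported as half-open [start, end)
# intervals. `start_time` is the time of the first sample.
runs_to_bouts <- function(flag, dt, min_bout, start_time = 0) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths * dt >= min_bout)
  out <- data.frame(
    start = start_time + (starts[keep] - 1L) * dt,
    end = start_time + ends[keep] * dt
  )
  out$duration <- out$end - out$start
  out
}

#' Detect sleep bouts in a velocity trace
#'
#' A sleep bout is a maximal run of consecutive tracked samples with velocity
#' at or below `eps` whose span is at least `min_bout` seconds — the
#' "velocity 0 mm/sec for at least 10 sec" rule, with `eps` absorbing
#' floating-point tracker jitter. Runs interrupted by untracked samples are
#' split; a motionless run touching a trace edge still counts if long enough.
#'
#' @param trace A [velocity_trace()].
#' @param min_bout Minimum bout span in seconds (default 10).
#' @param eps Motionless threshold in mm/sec (default 1e-3): a sample is
#'   motionless when `velocity <= eps`.
#' @return A data.frame of sleep bouts with columns `start`, `end`,
#'   `duration` (seconds, half-open intervals, ordered, non-overlapping).
#' @examples
#' tr <- velocity_trace(rep(0, 60), dt = 1)
#' detect_sleep_bouts(tr)  # one 60 s bout
#' @export
detect_sleep_bouts <- function(trace, min_bout = 10, eps = 1e-3) {
  if (!inherits(trace, "velocity_trace")) {
    stop_input("`trace` must be a velocity_trace")
  }
  check_scalar(min_bout, "min_bout", lower = 0, strict_lower = TRUE)
  check_scalar(eps, "eps", lower = 0)
  motionless <- trace$tracked & (trace$velocity <= eps)
  runs_to_bouts(motionless, trace$dt, min_bout, start_time = trace$t0)
}

#' Sleep bouts from a binary quiescence sequence
#'
#' Applies the same run-length rule as [detect_sleep_bouts()] to an
#' already-binarized series, e.g. per-frame-pair quiescence calls from the
#' chamber pipeline (where one pair spans 10 s, so every single quiescent
#' pair already meets the 10 s minimum).
#'
#' @param quiescent Logical vector, length >= 1 (`TRUE` = quiescent).
#' @param dt Seconds spanned by one element (> 0).
#' @param min_bout Minimum bout span in seconds (default 10).
#' @param t0 Time of the first element's interval start (default 0).
#' @return A data.frame of bouts (`start`, `end`, `duration` in seconds).
#' @examples
#' bouts_from_binary(c(TRUE, TRUE, FALSE, TRUE), dt = 10)
#' @export
bouts_from_binary <- function(quiescent, dt, min_bout = 10, t0 = 0) {
  if (length(quiescent) < 1L || !is.logical(quiescent) || anyNA(quiescent)) {
    stop_input("`quiescent` must be a non-empty logical vector without NA")
  }
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar(min_bout, "min_bout", lower = 0, strict_lower = TRUE)
  runs_to_bouts(quiescent, dt, min_bout, start_time = t0)
}
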