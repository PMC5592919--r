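#' Construct a chamber image stack
#'
#' A time-lapse recording of one animal in a microfluidic chamber: ordered
#' grayscale frames at a fixed interval (one frame per 10 s over up to 12 hr
#' in the screening protocol). Pixel values are stored as fractions of the
#' dynamic range, in `[0, 1]`, the convention of the tiff package.
#'
#' @param frames List of numeric matrices, all the same dimensions, values
#'   in `[0, 1]`; at least 2 frames.
#' @param frame_interval Seconds between frames (default 10).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval = 10) {
  if (!is.list(frames) || length(frames) < 2L) {
    stop_input("an image stack needs at least 2 frames")
  }
  if (!all(vapply(frames, is.matrix, TRUE))) {
    stop_input("every frame must be a 2-D grayscale matrix")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_input("all frames must have identical dimensions")
  }
  rng <- range(unlist(lapply(frames, range)))
  if (rng[1] < 0 || rng[2] > 1) {
    stop_input("pixel values must lie in [0, 1] (fraction of dynamic range)")
  }
  check_scalar(frame_interval, "frame_interval", lower = 0, strict_lower = TRUE)
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<image_stack> %d frames of %dx%d px @ %g s (%.2f hr)\n",
              length(x$frames), d[1], d[2], x$frame_interval,
              length(x$frames) * x$frame_interval / 3600))
  invisible(x)
}

#' Frame-subtraction quiescence calls
#'
#' For each consecutive frame pair, counts pixels whose absolute intensity
#' difference exceeds `pixel_thresh` (a fraction of the dynamic range); the
#' pair is called quiescent when at most `area_thresh` pixels changed. This
#' is the image-subtraction step of the chamber pipeline: a motionless
#' animal changes (almost) no pixels between frames 10 s apart.
#'
#' Pair `i` compares frames `i` and `i + 1`; its call covers the time
#' interval `[(i-1) * dt, i * dt)` where `dt` is the frame interval.
#'
#' @param stack An [image_stack()].
#' @param pixel_thresh Per-pixel change threshold as a fraction of the
#'   dynamic range, in (0, 1) (default 0.1).
#' @param area_thresh Maximum number of changed pixels for a quiescent pair
#'   (default 5).
#' @return Logical vector of length `n_frames - 1`; `TRUE` = quiescent.
#' @export
frame_subtract <- function(stack, pixel_thresh = 0.1, area_thresh = 5) {
  stopifnot(inherits(stack, "image_stack"))
  check_scalar(pixel_thresh, "pixel_thresh", lower = 0, upper = 1,
               strict_lower = TRUE)
  if (pixel_thresh >= 1) stop_input("`pixel_thresh` must be < 1")
  check_scalar(area_thresh, "area_thresh", lower = 0)
  n <- length(stack$frames)
  calls <- logical(n - 1L)
  for (i in seq_len(n - 1L)) {
    changed <- sum(abs(stack$frames[[i + 1L]] - stack$frames[[i]]) > pixel_thresh)
    calls[i] <- changed <= area_thresh
  }
  calls
}

#' Rolling fractional quiescence
#'
#' Rolling mean of binary quiescence calls over a centered window — with the
#' default 60 entries at 10 s per frame pair, a 10-min rolling average. At
#' index `i` the window is the full centered span of `window` entries
#' (`floor((window-1)/2)` before, the rest after) when it fits; nearer an
#' edge it shrinks symmetrically to `[i - m, i + m]` with
#' `m = min(i - 1, n - i)`, so the output has the same length as the input
#' and no systematic lag at the boundaries.
#'
#' @param calls Logical (or 0/1) vector of per-frame-pair quiescence calls.
#' @param window Window size in entries (default 60; >= 1).
#' @return Numeric vector of fractional quiescence values in `[0, 1]`,
#'   same length as `calls`.
#' @export
rolling_fq <- function(calls, window = 60) {
  if (!length(calls)) stop_input("`calls` must be non-empty")
  x <- as.numeric(calls)
  if (anyNA(x) || any(x < 0 | x > 1)) {
    stop_input("`calls` must be binary (logical or 0/1)")
  }
  window <- as.integer(check_scalar(window, "window", lower = 1))
  n <- length(x)
  before <- (window - 1L) %/% 2L
  after <- window - 1L - before
  cs <- cumsum(c(0, x))
  fq <- numeric(n)
  for (i in seq_len(n)) {
    m <- min(i - 1L, n - i)
    if (m >= after) {
      lo <- i - before
      hi <- i + after
    } else {
      lo <- i - m
      hi <- i + m
    }
    fq[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  fq
}

#' Detect the lethargus window from fractional quiescence
#'
#' Lethargus entry (`t_start`) is the first time from which fractional
#' quiescence stays above `threshold` continuously for at least `sustain`
#' seconds; exit (`t_end`) is the first time after entry from which it drops
#' to and stays at or below `threshold` for at least `sustain` seconds. A
#' below-threshold run that reaches the end of the recording qualifies as an
#' exit only if it is itself at least `sustain` long; otherwise the animal
#' is flagged censored (`t_end = NA`). Candidate entries earlier than
#' `min_onset` are rejected: animals are loaded at mid-L4, so behaviorally
#' defined lethargus must begin at least 1 hr into the recording.
#'
#' Index `i` of `fq` covers the time interval `[(i-1) * dt, i * dt)`;
#' boundary times are reported at interval starts.
#'
#' @param fq Numeric vector of fractional quiescence values in `[0, 1]`.
#' @param dt Seconds per entry (default 10).
#' @param threshold Fractional quiescence threshold (default 0.1).
#' @param sustain Required persistence in seconds (default 1200 = 20 min).
#' @param min_onset Earliest admissible entry time in seconds (default
#'   3600); set to 0 to disable.
#' @return An object of class `lethargus_window`: list with `t_start`,
#'   `t_end`, `duration` (seconds) and `censored` (logical), or `NULL` when
#'   no entry satisfies the rule (no lethargus detected).
#' @export
find_lethargus <- function(fq, dt = 10, threshold = 0.1, sustain = 1200,
                           min_onset = 3600) {
  if (!length(fq) || !is.numeric(fq)) stop_input("`fq` must be numeric")
  if (anyNA(fq) || any(fq < 0 | fq > 1)) {
    stop_input("`fq` values must lie in [0, 1]")
  }
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  check_scalar(sustain, "sustain", lower = 0, strict_lower = TRUE)
  check_scalar(min_onset, "min_onset", lower = 0)
  n <- length(fq)
  need <- as.integer(ceiling(sustain / dt))
  above <- fq > threshold

  # Length of the run of `above` (resp. !above) starting at each index.
  run_ahead <- function(flag) {
    out <- integer(n)
    nxt <- 0L
    for (i in n:1) {
      nxt <- if (flag[i]) nxt + 1L else 0L
      out[i] <- nxt
    }
    out
  }
  up <- run_ahead(above)
  down <- run_ahead(!above)

  start_idx <- which(up >= need & (seq_len(n) - 1L) * dt >= min_onset)
  if (!length(start_idx)) return(NULL)
  i0 <- start_idx[1L]
  t_start <- (i0 - 1L) * dt

  # exit: first below-run of >= `need` after entry; a run reaching the end
  # qualifies only by its own length.
  exit_idx <- which(down >= need & seq_len(n) > i0)
  if (length(exit_idx)) {
    i1 <- exit_idx[1L]
    t_end <- (i1 - 1L) * dt
    censored <- FALSE
  } else {
    t_end <- NA_real_
    censored <- TRUE
  }
  structure(list(t_start = t_start, t_end = t_end,
                 duration = t_end - t_start, censored = censored),
            class = "lethargus_window")
}

#' @export
print.lethargus_window <- function(x, ...) {
  if (x$censored) {
    cat(sprintf("<lethargus_window> entry %.0f s, exit censored\n", x$t_start))
  } else {
    cat(sprintf("<lethargus_window> [%.0f, %.0f) s (%.2f hr)\n",
                x$t_start, x$t_end, x$duration / 3600))
  }
  invisible(x)
}

#' Per-animal sleep metrics within a lethargus window
#'
#' Restricts the quiescence calls to `[t_start, t_end)`, segments sleep
#' bouts (>= `min_bout`) with [bouts_from_binary()], and reports total
#' sleep, bout count, mean sleep bout duration (total sleep / bout count)
#' and lethargus duration. Zero bouts inside a detected window is a valid
#' outcome: total sleep 0 and an undefined (NA) MSBD.
#'
#' @param calls Logical per-frame-pair quiescence calls.
#' @param dt Seconds per call (default 10).
#' @param window A `lethargus_window` from [find_lethargus()] (uncensored).
#' @param min_bout Minimum sleep-bout span in seconds (default 10).
#' @return One-row data.frame: `total_sleep_s`, `lethargus_duration_s`,
#'   `n_bouts`, `msbd_s`.
#' @export
animal_metrics <- function(calls, dt = 10, window, min_bout = 10) {
  stopifnot(inherits(window, "lethargus_window"))
  if (window$censored || is.na(window$t_end)) {
    stop_input("cannot compute sleep metrics for a censored lethargus window")
  }
  n <- length(calls)
  starts <- (seq_len(n) - 1L) * dt
  if (window$t_start < 0 || window$t_end > n * dt) {
    stop_input("lethargus window lies outside the call series")
  }
  keep <- starts >= window$t_start & starts < window$t_end
  sub <- as.logical(calls[keep])
  bouts <- if (length(sub)) bouts_from_binary(sub, dt, min_bout = min_bout)
           else data.frame(start = numeric(0), end = numeric(0),
                           duration = numeric(0))
  total_sleep <- sum(bouts$duration)
  n_bouts <- nrow(bouts)
  data.frame(
    total_sleep_s = total_sleep,
    lethargus_duration_s = window$duration,
    n_bouts = n_bouts,
    msbd_s = if (n_bouts > 0) total_sleep / n_bouts else NA_real_
  )
}

#' Full chamber pipeline for one animal
#'
#' Convenience wrapper: frame subtraction, rolling fractional quiescence,
#' lethargus boundary detection, and sleep metrics within the detected
#' window.
#'
#' @param stack An [image_stack()].
#' @param pixel_thresh,area_thresh Binarization thresholds, see
#'   [frame_subtract()].
#' @param fq_window Rolling window in frame pairs (default 60 = 10 min).
#' @param fq_threshold Lethargus threshold on fractional quiescence
#'   (default 0.1).
#' @param sustain Persistence requirement in seconds (default 1200).
#' @param min_onset Earliest admissible lethargus entry in seconds
#'   (default 3600).
#' @param min_bout Minimum sleep-bout span in seconds (default 10).
#' @return List with `calls`, `fq`, `window` (`NULL` if no lethargus) and
#'   `metrics` (one-row data.frame, or `NULL` when no uncensored window was
#'   found).
#' @export
analyze_stack <- function(stack, pixel_thresh = 0.1, area_thresh = 5,
                          fq_window = 60, fq_threshold = 0.1,
                          sustain = 1200, min_onset = 3600, min_bout = 10) {
  calls <- frame_subtract(stack, pixel_thresh, area_thresh)
  fq <- rolling_fq(calls, window = fq_window)
  window <- find_lethargus(fq, dt = stack$frame_interval,
                           threshold = fq_threshold, sustain = sustain,
                           min_onset = min_onset)
  metrics <- NULL
  if (!is.null(window) && !window$censored) {
    metrics <- animal_metrics(calls, dt = stack$frame_interval,
                              window = window, min_bout = min_bout)
  }
  list(calls = calls, fq = fq, window = window, metrics = metrics)
}
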