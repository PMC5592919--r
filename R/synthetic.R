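#' Parameters of the alternating sleep/motion bout process
#'
#' During L4-to-adult lethargus, C. elegans alternates between sleep bouts
#' and motion bouts; sleep occupies roughly 30% of lethargus. The simulator
#' models this as an alternating renewal process inside a programmed
#' lethargus window and continuous motion outside it. By default sleep bout
#' durations are drawn as `min_sleep_bout + Exponential` so that every
#' generated sleep bout survives the 10 s detection minimum and parameter
#' recovery is unbiased; the `"gamma"` family (shape 2, shifted the same
#' way) gives less skewed durations.
#'
#' The default motion-bout mean is derived from the sleep-fraction target:
#' `mean_motion_bout = mean_sleep_bout * (1 - f) / f`, about 46.7 s for the
#' defaults (target 0.30, mean sleep bout 20 s).
#'
#' @param sleep_fraction_target Long-run fraction of lethargus spent in
#'   sleep bouts (default 0.30), in (0, 1).
#' @param mean_sleep_bout Mean sleep-bout duration in seconds (default 20;
#'   must exceed `min_sleep_bout`).
#' @param mean_motion_bout Mean motion-bout duration in seconds; default
#'   derived from the target as above.
#' @param min_sleep_bout Hard minimum sleep-bout duration in seconds
#'   (default 10). Set below 10 only to study detection-filter bias
#'   deliberately.
#' @param lethargus_start,lethargus_end Programmed lethargus window in
#'   seconds (default 2 hr to 4.5 hr).
#' @param bout_duration_family `"exponential-shifted"` (default) or
#'   `"gamma"`.
#' @param tol Allowed relative mismatch between `sleep_fraction_target` and
#'   the fraction implied by the bout means (default 0.02).
#' @return A list of validated parameters, class `bout_params`.
#' @export
bout_params <- function(sleep_fraction_target = 0.30,
                        mean_sleep_bout = 20,
                        mean_motion_bout = NULL,
                        min_sleep_bout = 10,
                        lethargus_start = 7200,
                        lethargus_end = 16200,
                        bout_duration_family = c("exponential-shifted", "gamma"),
                        tol = 0.02) {
  check_scalar(sleep_fraction_target, "sleep_fraction_target",
               lower = 0, upper = 1, strict_lower = TRUE)
  if (sleep_fraction_target >= 1) {
    stop_input("`sleep_fraction_target` must be < 1")
  }
  check_scalar(min_sleep_bout, "min_sleep_bout", lower = 0)
  check_scalar(mean_sleep_bout, "mean_sleep_bout", lower = min_sleep_bout,
               strict_lower = TRUE)
  f <- sleep_fraction_target
  if (is.null(mean_motion_bout)) {
    mean_motion_bout <- mean_sleep_bout * (1 - f) / f
  }
  check_scalar(mean_motion_bout, "mean_motion_bout", lower = 0,
               strict_lower = TRUE)
  implied <- mean_sleep_bout / (mean_sleep_bout + mean_motion_bout)
  if (abs(implied - f) > tol * max(f, implied)) {
    stop_input(sprintf(
      "bout means imply sleep fraction %.3f, inconsistent with target %.3f",
      implied, f))
  }
  check_scalar(lethargus_start, "lethargus_start", lower = 0)
  check_scalar(lethargus_end, "lethargus_end", lower = lethargus_start,
               strict_lower = TRUE)
  structure(list(
    sleep_fraction_target = f,
    mean_sleep_bout = mean_sleep_bout,
    mean_motion_bout = mean_motion_bout,
    min_sleep_bout = min_sleep_bout,
    lethargus_start = lethargus_start,
    lethargus_end = lethargus_end,
    bout_duration_family = match.arg(bout_duration_family)
  ), class = "bout_params")
}

draw_sleep_durations <- function(n, params) {
  excess <- params$mean_sleep_bout - params$min_sleep_bout
  base <- switch(params$bout_duration_family,
    "exponential-shifted" = stats::rexp(n, rate = 1 / excess),
    "gamma" = stats::rgamma(n, shape = 2, scale = excess / 2)
  )
  params$min_sleep_bout + base
}

#' Simulate an alternating sleep/motion bout schedule
#'
#' Outside the programmed lethargus window the animal is in continuous
#' motion; inside it, sleep and motion bouts alternate with durations drawn
#' from the configured family (starting with a motion bout at lethargus
#' entry). Deterministic under a fixed seed.
#'
#' @param params A [bout_params()] object. A `sleep_fraction_target` of
#'   exactly 0 is accepted here as a degenerate all-motion schedule for
#'   testing (pass `sleep_fraction_target = 0` directly, bypassing
#'   [bout_params()] validation, via `all_motion = TRUE`).
#' @param duration Total schedule length in seconds (default 12 hr).
#' @param seed Optional integer seed (local to this call).
#' @param all_motion If `TRUE`, ignore the bout process and return a single
#'   motion segment (degenerate schedule for tests).
#' @return A data.frame with columns `start`, `end`, `state`
#'   (`"sleep"`/`"motion"`), ordered, non-overlapping, covering
#'   `[0, duration)`.
#' @export
simulate_bouts <- function(params, duration = 43200, seed = NULL,
                           all_motion = FALSE) {
  check_scalar(duration, "duration", lower = 0, strict_lower = TRUE)
  if (all_motion) {
    return(data.frame(start = 0, end = duration, state = "motion"))
  }
  stopifnot(inherits(params, "bout_params"))
  if (params$lethargus_start >= duration) {
    return(data.frame(start = 0, end = duration, state = "motion"))
  }
  with_seed(seed, {
    leth_end <- min(params$lethargus_end, duration)
    segs <- list()
    if (params$lethargus_start > 0) {
      segs[[1]] <- c(0, params$lethargus_start, 0)  # pre-lethargus motion
    }
    t <- params$lethargus_start
    sleeping <- FALSE  # enter lethargus in motion
    while (t < leth_end) {
      len <- if (sleeping) draw_sleep_durations(1L, params)
             else stats::rexp(1L, rate = 1 / params$mean_motion_bout)
      end <- min(t + len, leth_end)
      segs[[length(segs) + 1L]] <- c(t, end, as.numeric(sleeping))
      t <- end
      sleeping <- !sleeping
    }
    if (leth_end < duration) {
      segs[[length(segs) + 1L]] <- c(leth_end, duration, 0)
    }
    m <- do.call(rbind, segs)
    sched <- data.frame(start = m[, 1], end = m[, 2],
                        state = ifelse(m[, 3] > 0, "sleep", "motion"))
    # merge adjacent same-state segments (e.g. post-lethargus motion after
    # a clipped motion bout)
    keep <- c(TRUE, sched$state[-1] != sched$state[-nrow(sched)])
    grp <- cumsum(keep)
    data.frame(
      start = tapply(sched$start, grp, min),
      end = tapply(sched$end, grp, max),
      state = sched$state[keep],
      row.names = NULL
    )
  })
}

#' Render a bout schedule as a velocity trace
#'
#' Velocity is exactly 0 mm/sec during sleep bouts (matching the bout
#' definition) and a positive speed during motion bouts, drawn per sample
#' from a normal distribution truncated at zero. An optional jitter adds
#' small positive noise to sleep samples to exercise the `eps` tolerance of
#' the detector.
#'
#' @param schedule Bout schedule data.frame from [simulate_bouts()].
#' @param dt Sampling interval in seconds (default 1).
#' @param motion_speed_mean,motion_speed_sd Motion-speed distribution in
#'   mm/sec (defaults 0.15 and 0.05, typical adult crawling speeds).
#' @param sleep_jitter_sd SD of non-negative velocity jitter added to sleep
#'   samples (default 0 = exact zeros).
#' @param seed Optional integer seed (local to this call).
#' @param animal_id Identifier for the emitted trace.
#' @return A [velocity_trace()] sampled at `dt` covering the schedule.
#' @export
bouts_to_velocity <- function(schedule, dt = 1, motion_speed_mean = 0.15,
                              motion_speed_sd = 0.05, sleep_jitter_sd = 0,
                              seed = NULL, animal_id = "sim") {
  if (!all(c("start", "end", "state") %in% names(schedule)) ||
      !nrow(schedule)) {
    stop_input("`schedule` must have rows with start, end, state")
  }
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  total <- max(schedule$end)
  times <- seq(0, total - dt / 2, by = dt)
  idx <- findInterval(times, schedule$start)
  asleep <- schedule$state[idx] == "sleep"
  with_seed(seed, {
    v <- numeric(length(times))
    n_mot <- sum(!asleep)
    if (n_mot) {
      v[!asleep] <- pmax(0, stats::rnorm(n_mot, motion_speed_mean,
                                         motion_speed_sd))
    }
    if (sleep_jitter_sd > 0 && any(asleep)) {
      v[asleep] <- abs(stats::rnorm(sum(asleep), 0, sleep_jitter_sd))
    }
    velocity_trace(v, dt = dt, t0 = 0, animal_id = animal_id)
  })
}

#' Rendering parameters for synthetic chamber stacks
#'
#' @param img_size Frame side length in pixels (square frames, default 64).
#' @param blob_radius Radius of the rendered animal blob in pixels
#'   (default 4).
#' @param step_px Random-walk step length per frame during motion bouts, in
#'   pixels (default 10; should exceed the blob diameter so motion is
#'   unambiguous to frame subtraction).
#' @param noise_amp Amplitude of uniform pixel noise as a fraction of the
#'   dynamic range (default 0.02; keep below the frame-subtraction
#'   `pixel_thresh`).
#' @param frame_interval Seconds between frames (default 10).
#' @return A validated list, class `render_params`.
#' @export
render_params <- function(img_size = 64, blob_radius = 4, step_px = 10,
                          noise_amp = 0.02, frame_interval = 10) {
  check_scalar(img_size, "img_size", lower = 8)
  check_scalar(blob_radius, "blob_radius", lower = 1)
  check_scalar(step_px, "step_px", lower = 0)
  check_scalar(noise_amp, "noise_amp", lower = 0, upper = 0.5)
  check_scalar(frame_interval, "frame_interval", lower = 0,
               strict_lower = TRUE)
  if (img_size < 4 * blob_radius) {
    stop_input("frame too small for the blob: need img_size >= 4*blob_radius")
  }
  structure(list(img_size = as.integer(img_size), blob_radius = blob_radius,
                 step_px = step_px, noise_amp = noise_amp,
                 frame_interval = frame_interval), class = "render_params")
}

disk_frame <- function(size, cx, cy, radius) {
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  f <- matrix(0, size, size)
  f[(xs - cx)^2 + (ys - cy)^2 <= radius^2] <- 0.8
  f
}

#' Render a bout schedule as a chamber image stack
#'
#' Draws the animal as a hard disk on a dark background: stationary during
#' sleep bouts, taking random-walk steps of `step_px` pixels (random
#' direction, reflected at the frame boundary) once per frame during motion
#' bouts. Sub-threshold uniform noise is added to every frame. Frame
#' subtraction only needs displacement, so no worm morphology is modeled.
#'
#' @param schedule Bout schedule from [simulate_bouts()].
#' @param render A [render_params()] object.
#' @param duration Recording length in seconds (default: schedule extent).
#' @param seed Optional integer seed (local to this call).
#' @return An [image_stack()].
#' @export
render_stack <- function(schedule, render = render_params(),
                         duration = NULL, seed = NULL) {
  stopifnot(inherits(render, "render_params"))
  if (is.null(duration)) duration <- max(schedule$end)
  n_frames <- as.integer(floor(duration / render$frame_interval)) + 1L
  if (n_frames < 2L) stop_input("duration too short for 2 frames")
  size <- render$img_size
  margin <- render$blob_radius + 1
  with_seed(seed, {
    cx <- size / 2
    cy <- size / 2
    frames <- vector("list", n_frames)
    for (j in seq_len(n_frames)) {
      t_frame <- (j - 1L) * render$frame_interval
      if (j > 1L) {
        idx <- findInterval(min(t_frame, max(schedule$end) - 1e-9),
                            schedule$start)
        if (schedule$state[idx] == "motion" && render$step_px > 0) {
          ang <- stats::runif(1, 0, 2 * pi)
          cx <- cx + render$step_px * cos(ang)
          cy <- cy + render$step_px * sin(ang)
          # reflect at boundaries, keeping the blob fully inside
          reflect <- function(z) {
            lo <- margin; hi <- size - margin
            span <- 2 * (hi - lo)
            z <- (z - lo) %% span
            if (z > hi - lo) z <- span - z
            z + lo
          }
          cx <- reflect(cx)
          cy <- reflect(cy)
        }
      }
      f <- disk_frame(size, cx, cy, render$blob_radius)
      if (render$noise_amp > 0) {
        f <- f + matrix(stats::runif(size * size, 0, render$noise_amp),
                        size, size)
      }
      frames[[j]] <- pmin(f, 1)
    }
    image_stack(frames, frame_interval = render$frame_interval)
  })
}

#' Simulate primary-screen plate scores
#'
#' Bernoulli plate scoring: each plate scores `n_scored` young adults, each
#' Ans with probability `ans_rate` (0.60 for control animals under
#' screening conditions; lower for genuine suppressor lines).
#'
#' @param n_lines Number of plates/lines.
#' @param ans_rate Per-animal Ans probability in `[0, 1]` (default 0.60).
#' @param n_scored Animals scored per plate (default 10, the protocol
#'   maximum).
#' @param seed Optional integer seed (local to this call).
#' @param prefix Line-id prefix (default "line").
#' @return Data.frame: `line_id`, `n_ans`, `n_scored`.
#' @export
simulate_plates <- function(n_lines, ans_rate = 0.60, n_scored = 10,
                            seed = NULL, prefix = "line") {
  check_scalar(n_lines, "n_lines", lower = 1)
  check_scalar(ans_rate, "ans_rate", lower = 0, upper = 1)
  check_scalar(n_scored, "n_scored", lower = 1)
  with_seed(seed, {
    data.frame(
      line_id = sprintf("%s%04d", prefix, seq_len(n_lines)),
      n_ans = stats::rbinom(n_lines, size = n_scored, prob = ans_rate),
      n_scored = as.integer(n_scored)
    )
  })
}

#' Simulate per-line screen outcomes for funnel accounting
#'
#' Draws independent Bernoulli stage outcomes per line at the supplied
#' pass rates, conditioning each stage on survival of the previous ones
#' (lines that drop out have `NA` outcomes downstream). Defaults are the
#' empirical stage rates of the published screen funnel
#' (2132 -> 292 -> 118 -> 79 -> 32 -> 16).
#'
#' @param n_lines Number of F2 lines (default 2132).
#' @param p_primary Primary retention probability (default 292/2132).
#' @param p_rescreen Rescreen pass probability given primary (default
#'   118/292).
#' @param p_independent Probability a rescreened line is kept as
#'   independent (default 79/118).
#' @param p_tested Probability an independent line reaches the tertiary
#'   assay, i.e. is selected by the secondary screen or untrackable
#'   (default 32/79).
#' @param p_untrackable_given_tested Fraction of tertiary-tested lines that
#'   bypassed the tracker for size/posture/locomotion reasons (default
#'   11/32).
#' @param p_hit Tertiary confirmation probability given tested (default
#'   16/32).
#' @param seed Optional integer seed (local to this call).
#' @return A data.frame suitable for [funnel_report()].
#' @export
simulate_screen_lines <- function(n_lines = 2132,
                                  p_primary = 292 / 2132,
                                  p_rescreen = 118 / 292,
                                  p_independent = 79 / 118,
                                  p_tested = 32 / 79,
                                  p_untrackable_given_tested = 11 / 32,
                                  p_hit = 16 / 32,
                                  seed = NULL) {
  check_scalar(n_lines, "n_lines", lower = 1)
  for (p in c(p_primary, p_rescreen, p_independent, p_tested,
              p_untrackable_given_tested, p_hit)) {
    check_scalar(p, "stage probability", lower = 0, upper = 1)
  }
  with_seed(seed, {
    n <- as.integer(n_lines)
    bern <- function(p, cond) cond & (stats::runif(n) < p)
    s1 <- stats::runif(n) < p_primary
    s2 <- bern(p_rescreen, s1)
    s3 <- bern(p_independent, s2)
    s4 <- bern(p_tested, s3)
    untrack <- bern(p_untrackable_given_tested, s4)
    status <- rep("not_selected", n)
    status[s4] <- ifelse(untrack[s4], "untrackable", "selected")
    hit <- bern(p_hit, s4)
    data.frame(
      line_id = sprintf("line%04d", seq_len(n)),
      primary_retained = s1,
      rescreen_passed = s2,
      independent = s3,
      secondary_status = status,
      tertiary_defect = ifelse(s4, hit, NA)
    )
  })
}
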