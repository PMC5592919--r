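#' Write velocity traces to CSV
#'
#' One file may hold many animals; columns are `animal_id`, `time_s`,
#' `velocity_mm_s` and `tracked` (0/1). Comma-separated, header row, '.'
#' decimal, UTF-8.
#'
#' @param traces A [velocity_trace()] or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  if (inherits(traces, "velocity_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(
      animal_id = tr$animal_id,
      time_s = tr$t0 + (seq_along(tr$velocity) - 1L) * tr$dt,
      velocity_mm_s = tr$velocity,
      tracked = as.integer(tr$tracked)
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read velocity traces from CSV
#'
#' Reads the format written by [write_traces()]: columns `animal_id`,
#' `time_s`, `velocity_mm_s`, optional `tracked` (0/1). Rows are grouped by
#' animal and sorted by time; the sampling interval is inferred from the
#' time stamps and must be uniform per animal. Negative velocities and
#' duplicate time stamps are rejected with the offending row named.
#'
#' @param path CSV file path.
#' @return Named list of [velocity_trace()] objects, one per animal.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "time_s", "velocity_mm_s")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_input("trace file is missing columns: ",
               paste(missing, collapse = ", "))
  }
  if (!nrow(df)) stop_input("trace file contains no rows")
  if (is.null(df$tracked)) df$tracked <- 1L
  bad <- which(df$tracked == 1L & df$velocity_mm_s < 0)
  if (length(bad)) {
    stop_input(sprintf("negative velocity at row %d of %s", bad[1], path))
  }
  out <- lapply(split(df, df$animal_id), function(g) {
    g <- g[order(g$time_s), ]
    if (anyDuplicated(g$time_s)) {
      stop_input(sprintf("duplicate time stamp for animal %s",
                         g$animal_id[1]))
    }
    if (nrow(g) > 1L) {
      steps <- diff(g$time_s)
      if (max(steps) - min(steps) > 1e-6 * max(steps)) {
        stop_input(sprintf("non-uniform sampling interval for animal %s",
                           g$animal_id[1]))
      }
      dt <- stats::median(steps)
    } else {
      dt <- 1
    }
    velocity_trace(g$velocity_mm_s, dt = dt, t0 = g$time_s[1],
                   animal_id = g$animal_id[1], tracked = g$tracked == 1L)
  })
  out[order(names(out))]
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param bits_per_sample 8 or 16 (default 8).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits_per_sample = 8) {
  stopifnot(inherits(stack, "image_stack"))
  tiff::writeTIFF(stack$frames, path, bits.per.sample = bits_per_sample)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' @param path TIFF file path (8- or 16-bit grayscale, >= 2 pages, all the
#'   same dimensions).
#' @param frame_interval Seconds between frames (default 10); supply the
#'   acquisition interval since TIFF files carry no timing metadata.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, frame_interval = 10) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  if (length(frames) < 2L) {
    stop_input("image stack needs >= 2 frames")
  }
  if (any(vapply(frames, function(f) length(dim(f)), 0L) != 2L)) {
    stop_input("frames are not grayscale; convert RGB images to grayscale first")
  }
  image_stack(frames, frame_interval = frame_interval)
}

#' Validated run configuration
#'
#' Collects every tunable parameter of the pipeline with its default;
#' unknown keys are rejected. The configuration serializes to canonical
#' JSON and carries an MD5 hash so that outputs can embed the effective
#' configuration: equal hashes imply equal parameterizations.
#'
#' @param ... Overrides for any known parameter (see defaults in the
#'   source: bout detection, metrics window, chamber thresholds, lethargus
#'   rule, triage thresholds, simulator seed).
#' @return List of parameters, class `run_config`, with attributes `json`
#'   and `hash`.
#' @export
run_config <- function(...) {
  defaults <- list(
    min_bout = 10, eps = 1e-3,
    window_start = 0, window_length = 600,
    pixel_thresh = 0.1, area_thresh = 5,
    fq_window = 60, fq_threshold = 0.1, sustain = 1200, min_onset = 3600,
    frame_interval = 10,
    max_ans_fraction = 0.30, secondary_k = 2, alpha = 0.05,
    n_animals = 30, seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop_input("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, overrides)
  for (key in c("min_bout", "window_length", "fq_window", "sustain",
                "frame_interval")) {
    check_scalar(cfg[[key]], key, lower = 0, strict_lower = TRUE)
  }
  check_scalar(cfg$eps, "eps", lower = 0)
  check_scalar(cfg$pixel_thresh, "pixel_thresh", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_scalar(cfg$area_thresh, "area_thresh", lower = 0)
  check_scalar(cfg$fq_threshold, "fq_threshold", lower = 0, upper = 1)
  check_scalar(cfg$max_ans_fraction, "max_ans_fraction", lower = 0, upper = 1)
  check_scalar(cfg$alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  json <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                           digits = NA)
  tmp <- tempfile()
  writeLines(as.character(json), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  structure(cfg, class = "run_config", json = as.character(json),
            hash = hash)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>", attr(x, "hash"), "\n")
  cat(attr(x, "json"), "\n")
  invisible(x)
}

#' Simulate-analyze-triage smoke pipeline
#'
#' Runs the whole workflow on synthetic data under one configuration:
#' simulates a small population of mid-lethargus animals, computes pooled
#' population sleep metrics over the sampling window, simulates control and
#' suppressed primary-screen plates and applies the retention rule, and
#' returns a summary bundle embedding the effective configuration hash.
#' Identical configurations (hence identical seeds) give identical
#' summaries.
#'
#' @param config A [run_config()].
#' @return List: `config_hash`, `metrics` (population metrics data.frame),
#'   `plates` (data.frame with a `retained` column), `n_retained`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  params <- bout_params(lethargus_start = 0,
                        lethargus_end = config$window_length)
  traces <- lapply(seq_len(config$n_animals), function(i) {
    sched <- simulate_bouts(params, duration = config$window_length,
                            seed = config$seed * 1000L + i)
    bouts_to_velocity(sched, dt = 1, seed = config$seed * 1000L + i,
                      animal_id = sprintf("a%03d", i))
  })
  windows <- lapply(traces, sample_window, start = config$window_start,
                    length = config$window_length)
  metrics <- population_metrics(windows, min_bout = config$min_bout,
                                eps = config$eps)
  plates <- simulate_plates(50, ans_rate = 0.60, seed = config$seed + 7L)
  plates$retained <- ans_retention(plates$n_ans, plates$n_scored,
                                   max_fraction = config$max_ans_fraction)
  list(
    config_hash = attr(config, "hash"),
    metrics = metrics,
    plates = plates,
    n_retained = sum(plates$retained)
  )
}
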