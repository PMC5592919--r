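flat_stack <- function(n, value = 0.5, size = 16, dt = 10) {
  image_stack(replicate(n, matrix(value, size, size), simplify = FALSE),
              frame_interval = dt)
}

test_that("frame subtraction calls quiescence from pixel change counts", {
  # identical frames: zero difference, every pair quiescent
  expect_true(all(frame_subtract(flat_stack(10))))

  # blob displaced by more than its own diameter: ~2x blob area changed
  sched <- data.frame(start = 0, end = 100, state = "motion")
  st <- render_stack(sched, render_params(step_px = 12, blob_radius = 4,
                                          noise_amp = 0), seed = 5)
  expect_true(all(!frame_subtract(st)))

  # sub-threshold uniform noise never trips the pixel threshold
  set.seed(31)
  noisy <- lapply(1:8, function(i) matrix(runif(256, 0, 0.05), 16, 16))
  expect_true(all(frame_subtract(image_stack(noisy), pixel_thresh = 0.1)))
})

test_that("changed-pixel counting matches a per-pixel brute force", {
  set.seed(32)
  frames <- lapply(1:12, function(i) matrix(runif(100), 10, 10))
  st <- image_stack(frames)
  for (area_thresh in c(0, 10, 50)) {
    got <- frame_subtract(st, pixel_thresh = 0.3, area_thresh = area_thresh)
    want <- logical(11)
    for (i in 1:11) {
      cnt <- 0L
      for (r in 1:10) for (cc in 1:10) {
        if (abs(frames[[i + 1]][r, cc] - frames[[i]][r, cc]) > 0.3) {
          cnt <- cnt + 1L
        }
      }
      want[i] <- cnt <= area_thresh
    }
    expect_equal(got, want)
  }
})

test_that("raising area_thresh never decreases the number of quiescent pairs", {
  set.seed(33)
  frames <- lapply(1:20, function(i) matrix(runif(64), 8, 8))
  st <- image_stack(frames)
  counts <- sapply(c(0, 2, 5, 10, 30, 64),
                   function(a) sum(frame_subtract(st, 0.2, a)))
  expect_true(all(diff(counts) >= 0))
})

test_that("rolling fractional quiescence matches brute-force windowed means", {
  expect_equal(rolling_fq(rep(TRUE, 100)), rep(1, 100))

  # strictly alternating calls: interior values 0.5 by symmetry
  alt <- rep(c(TRUE, FALSE), 50)
  fq <- rolling_fq(alt, window = 4)
  expect_true(all(abs(fq[3:97] - 0.5) < 1e-12))

  set.seed(34)
  x <- runif(1000) < 0.4
  for (w in c(1, 2, 7, 60)) {
    expect_equal(rolling_fq(x, window = w), oracle_rolling_mean(x, w))
  }
})

test_that("fq lies in [0,1] and complementing the calls reflects it", {
  set.seed(35)
  x <- runif(500) < 0.3
  fq <- rolling_fq(x)
  expect_true(all(fq >= 0 & fq <= 1))
  expect_equal(rolling_fq(!x), 1 - fq)
})

test_that("square-wave fractional quiescence gives exact lethargus boundaries", {
  # 1 hr at 0, 2 hr at 0.5, 1 hr at 0 (dt = 10 s)
  fq <- c(rep(0, 360), rep(0.5, 720), rep(0, 360))
  w <- find_lethargus(fq, dt = 10)
  expect_equal(w$t_start, 3600)
  expect_equal(w$t_end, 10800)
  expect_equal(w$duration, 7200)
  expect_false(w$censored)
})

test_that("the 20-min sustain rule rejects brief excursions and flat traces", {
  # quiescence never above threshold: no lethargus
  expect_null(find_lethargus(rep(0.05, 2000), dt = 10))

  # a 10-min excursion above threshold is not an entry
  fq <- c(rep(0, 400), rep(0.5, 60), rep(0, 1000))
  expect_null(find_lethargus(fq, dt = 10))

  # exactly 20 min above threshold after the onset floor qualifies
  fq <- c(rep(0, 400), rep(0.5, 120), rep(0, 300))
  w <- find_lethargus(fq, dt = 10)
  expect_equal(w$t_start, 4000)
  expect_equal(w$t_end, 5200)
})

test_that("exit censoring distinguishes missing from trailing exits", {
  # quiescence persists to the end of the recording: exit undefined
  fq <- c(rep(0, 400), rep(0.5, 1200))
  w <- find_lethargus(fq, dt = 10)
  expect_true(w$censored)
  expect_true(is.na(w$t_end))

  # a trailing below-threshold run >= 20 min is a proper exit
  fq2 <- c(rep(0, 400), rep(0.5, 1200), rep(0, 120))
  w2 <- find_lethargus(fq2, dt = 10)
  expect_false(w2$censored)
  expect_equal(w2$t_end, 16000)

  # a trailing below-threshold run of only 10 min is not
  fq3 <- c(rep(0, 400), rep(0.5, 1200), rep(0, 60))
  expect_true(find_lethargus(fq3, dt = 10)$censored)
})

test_that("raising the fq threshold never advances lethargus entry", {
  set.seed(36)
  base <- stats::filter(runif(2000, 0, 0.5), rep(1 / 30, 30), sides = 2)
  base[is.na(base)] <- 0
  fq <- pmin(pmax(as.numeric(base), 0), 1)
  prev <- -Inf
  for (thr in c(0.05, 0.1, 0.15, 0.2)) {
    w <- find_lethargus(fq, dt = 10, threshold = thr, min_onset = 0)
    if (is.null(w)) break
    expect_gte(w$t_start, prev)
    prev <- w$t_start
  }
})

test_that("per-animal sleep metrics follow run-length arithmetic", {
  # a single 1-hr quiescent run inside a 2-hr window
  calls <- c(rep(FALSE, 100), rep(TRUE, 360), rep(FALSE, 360))
  w <- structure(list(t_start = 1000, t_end = 1000 + 7200, duration = 7200,
                      censored = FALSE), class = "lethargus_window")
  m <- animal_metrics(calls, dt = 10, window = w)
  expect_equal(m$total_sleep_s, 3600)
  expect_equal(m$n_bouts, 1L)
  expect_equal(m$msbd_s, 3600)
  expect_equal(m$lethargus_duration_s, 7200)

  # alternating quiescent/active pairs across a 2-hr window
  calls2 <- rep(c(TRUE, FALSE), 360)
  w2 <- structure(list(t_start = 0, t_end = 7200, duration = 7200,
                       censored = FALSE), class = "lethargus_window")
  m2 <- animal_metrics(calls2, dt = 10, window = w2)
  expect_equal(m2$total_sleep_s, 3600)
  expect_equal(m2$n_bouts, 360L)
  expect_equal(m2$msbd_s, 10)

  # zero bouts inside a detected window is a value, not an error
  m3 <- animal_metrics(rep(FALSE, 720), dt = 10, window = w2)
  expect_equal(m3$total_sleep_s, 0)
  expect_true(is.na(m3$msbd_s))

  # total sleep can never exceed the lethargus duration
  expect_lte(m2$total_sleep_s, m2$lethargus_duration_s)
})

test_that("the full chamber pipeline recovers a programmed lethargus", {
  params <- bout_params()  # lethargus programmed at [7200, 16200] s
  for (s in 1:2) {
    sched <- simulate_bouts(params, duration = 23400, seed = s)
    st <- render_stack(sched, render_params(), duration = 23400,
                       seed = s + 100)
    res <- analyze_stack(st)
    expect_false(is.null(res$window))
    expect_false(res$window$censored)
    expect_lt(abs(res$window$t_start - 7200), 600)
    expect_lt(abs(res$window$t_end - 16200), 600)
    expect_lte(res$metrics$total_sleep_s, res$metrics$lethargus_duration_s)
  }
})
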