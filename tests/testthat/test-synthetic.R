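test_that("bout parameter validation catches inconsistent settings", {
  p <- bout_params()
  expect_equal(p$mean_motion_bout, 20 * 0.7 / 0.3, tolerance = 1e-12)
  expect_error(bout_params(sleep_fraction_target = 0), "sleep_fraction_target")
  expect_error(bout_params(mean_sleep_bout = 5, min_sleep_bout = 10),
               "mean_sleep_bout")
  # motion mean wildly inconsistent with the target fraction
  expect_error(bout_params(mean_motion_bout = 200), "inconsistent")
  expect_error(bout_params(lethargus_start = 100, lethargus_end = 50),
               "lethargus_end")
})

test_that("simulated schedules are contiguous, alternating and seeded", {
  p <- bout_params()
  s1 <- simulate_bouts(p, duration = 30000, seed = 51)
  s2 <- simulate_bouts(p, duration = 30000, seed = 51)
  expect_identical(s1, s2)  # byte-identical under a fixed seed
  expect_false(identical(s1, simulate_bouts(p, duration = 30000, seed = 52)))

  expect_equal(s1$start[1], 0)
  expect_equal(s1$end[nrow(s1)], 30000)
  expect_equal(s1$start[-1], s1$end[-nrow(s1)])  # contiguous
  expect_true(all(s1$state[-1] != s1$state[-nrow(s1)]))  # alternating
  # no sleep outside the programmed lethargus window
  sleep <- s1[s1$state == "sleep", ]
  expect_true(all(sleep$start >= p$lethargus_start))
  expect_true(all(sleep$end <= p$lethargus_end))
  # every sleep bout respects the hard minimum (the one ending exactly at
  # lethargus exit may be clipped)
  interior <- sleep[sleep$end < p$lethargus_end, ]
  expect_true(all(interior$end - interior$start >= p$min_sleep_bout - 1e-9))

  # degenerate all-motion schedule
  s0 <- simulate_bouts(p, duration = 1000, all_motion = TRUE)
  expect_equal(s0$state, "motion")
})

test_that("the gamma bout family also hits its sleep-fraction target", {
  p <- bout_params(bout_duration_family = "gamma")
  sched <- simulate_bouts(p, duration = 43200, seed = 53)
  sleep <- sched[sched$state == "sleep", ]
  frac <- sum(sleep$end - sleep$start) /
    (p$lethargus_end - p$lethargus_start)
  expect_lt(abs(frac - 0.30), 0.08)  # single animal, loose bound
})

test_that("pooled schedule sleep fraction matches the generator target", {
  p <- bout_params()
  sleep_tot <- 0
  for (i in 1:50) {
    sched <- simulate_bouts(p, duration = 20000, seed = 5000 + i)
    sl <- sched[sched$state == "sleep", ]
    sleep_tot <- sleep_tot + sum(sl$end - sl$start)
  }
  frac <- sleep_tot / (50 * (16200 - 7200))
  expect_lt(abs(frac - 0.30), 0.012)  # ~4 SE at this problem size
})

test_that("velocity rendering round-trips a boundary-aligned schedule", {
  sched <- data.frame(
    start = c(0, 30, 60, 100, 120),
    end = c(30, 60, 100, 120, 150),
    state = c("motion", "sleep", "motion", "sleep", "motion")
  )
  tr <- bouts_to_velocity(sched, dt = 1, seed = 54)
  expect_equal(length(tr$velocity), 150)
  b <- detect_sleep_bouts(tr)
  expect_equal(b$start, c(30, 100))
  expect_equal(b$end, c(60, 120))

  # all-sleep schedule: an all-zero trace; all-motion: no bouts at all
  allsleep <- data.frame(start = 0, end = 120, state = "sleep")
  expect_true(all(bouts_to_velocity(allsleep, dt = 1)$velocity == 0))
  allmot <- data.frame(start = 0, end = 120, state = "motion")
  tm <- bouts_to_velocity(allmot, dt = 1, seed = 55)
  expect_equal(nrow(detect_sleep_bouts(tm)), 0L)

  # jitter mode exercises the eps tolerance
  tj <- bouts_to_velocity(sched, dt = 1, sleep_jitter_sd = 2e-4, seed = 56)
  bj <- detect_sleep_bouts(tj, eps = 1e-3)
  expect_equal(bj$start, c(30, 100))
})

test_that("rendered stacks are quiescent asleep and active in motion", {
  allsleep <- data.frame(start = 0, end = 300, state = "sleep")
  st <- render_stack(allsleep, render_params(noise_amp = 0.02), seed = 57)
  expect_true(all(frame_subtract(st)))

  allmot <- data.frame(start = 0, end = 300, state = "motion")
  st2 <- render_stack(allmot, render_params(step_px = 12, noise_amp = 0.02),
                      seed = 58)
  expect_true(all(!frame_subtract(st2)))

  # determinism of the renderer
  st3 <- render_stack(allmot, render_params(), seed = 59)
  st4 <- render_stack(allmot, render_params(), seed = 59)
  expect_identical(st3$frames, st4$frames)
})

test_that("simulated plates follow the binomial scoring model", {
  expect_true(all(!ans_retention(simulate_plates(50, ans_rate = 1,
                                                 seed = 60)$n_ans,
                                 rep(10, 50))))
  expect_true(all(ans_retention(simulate_plates(50, ans_rate = 0,
                                                seed = 61)$n_ans,
                                rep(10, 50))))
  p1 <- simulate_plates(100, seed = 62)
  expect_identical(p1, simulate_plates(100, seed = 62))

  # control plates at 60% Ans: retention rate equals the binomial tail
  plates <- simulate_plates(10000, ans_rate = 0.60, n_scored = 10, seed = 63)
  rate <- mean(ans_retention(plates$n_ans, plates$n_scored))
  expected <- pbinom(3, 10, 0.6)
  expect_lt(abs(rate - expected), 3 * sqrt(expected * (1 - expected) / 10000))
})

test_that("every emitted artifact is readable by the package's own readers", {
  p <- bout_params(lethargus_start = 0, lethargus_end = 600)
  sched <- simulate_bouts(p, duration = 600, seed = 64)
  tr <- bouts_to_velocity(sched, dt = 1, seed = 64, animal_id = "rt")
  f <- tempfile(fileext = ".csv")
  write_traces(tr, f)
  back <- read_traces(f)[["rt"]]
  expect_equal(back$velocity, tr$velocity)
  expect_equal(back$dt, tr$dt)
  unlink(f)

  st <- render_stack(sched[1:3, ], render_params(noise_amp = 0), seed = 65,
                     duration = 100)
  tf <- tempfile(fileext = ".tif")
  write_stack(st, tf)
  st_back <- read_stack(tf, frame_interval = 10)
  expect_equal(length(st_back$frames), length(st$frames))
  expect_equal(st_back$frames[[1]], st$frames[[1]], tolerance = 1 / 255)
  unlink(tf)
})
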