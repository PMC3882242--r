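test_that("wave-event detection matches closed-form traces", {
  # flat resting trace: no events
  flat <- tibble::tibble(time = seq(0, 100, 0.5), K = 0.03)
  expect_equal(nrow(detect_wave_events(flat)), 0)
  # Gaussian pulse: exactly one event with known peak
  tt <- seq(0, 200, 0.25)
  gauss <- tibble::tibble(time = tt, K = 0.03 + 0.97 * exp(-(tt - 100)^2 / 50))
  ev <- detect_wave_events(gauss)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_time, 100)
  expect_equal(ev$peak_value, 1, tolerance = 1e-6)
  expect_lt(ev$onset_time, 100)
  expect_gt(ev$offset_time, 100)
  # crossing times are interpolated: K = 0.2 when (t-100)^2 = 50*log(0.97/0.17)
  half_width <- sqrt(50 * log(0.97 / 0.17))
  expect_equal(ev$onset_time, 100 - half_width, tolerance = 0.3)
  # two separated pulses give two events; an unfinished pulse has NA offset
  two <- tibble::tibble(time = tt,
                        K = 0.03 + 0.97 * (exp(-(tt - 50)^2 / 20) +
                                             exp(-(tt - 198)^2 / 20)))
  ev2 <- detect_wave_events(two)
  expect_equal(nrow(ev2), 2)
  expect_true(is.na(ev2$offset_time[2]))
  expect_error(detect_wave_events(tibble::tibble(time = c(1, 1), K = c(0, 1))),
               "strictly increasing")
})

test_that("regime classification follows the pairing rules", {
  mk <- function(onsets, tmax = 3000) {
    tt <- seq(0, tmax, 1)
    K <- rep(0.03, length(tt))
    for (o in onsets) K <- K + 0.9 * exp(-(tt - o)^2 / 100)
    tibble::tibble(time = tt, K = K)
  }
  # both probes see both waves at the same time: homogeneous
  cl <- classify_regime(mk(c(400, 1400)), mk(c(400, 1400)), n_waves = 2,
                        window = 1000)
  expect_equal(cl$regime, c("homogeneous", "homogeneous"))
  # second wave missing at the modulated probe: blocked
  cl <- classify_regime(mk(c(400, 1400)), mk(400), n_waves = 2, window = 1000)
  expect_equal(cl$regime, c("homogeneous", "blocked"))
  expect_true(is.na(cl$modulated_onset[2]))
  # delayed second onset beyond the margin: slowed
  cl <- classify_regime(mk(c(400, 1400)), mk(c(400, 1450)), n_waves = 2,
                        window = 1000, delta = 1)
  expect_equal(cl$regime, c("homogeneous", "slowed"))
  expect_equal(cl$delay[2], 50, tolerance = 1)
  # delay below the margin stays homogeneous
  cl <- classify_regime(mk(c(400, 1400)), mk(c(400, 1400.5)), n_waves = 2,
                        window = 1000, delta = 1)
  expect_equal(cl$regime[2], "homogeneous")
})

test_that("propagation speed recovers a constructed front velocity", {
  # synthetic snapshots: circular front at radius 0.4 * t (cells), dx = 1
  times <- seq(10, 60, 5)
  n <- 60
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  rad <- sqrt((rows - 30)^2 + (cols - 30)^2)
  K <- array(0.03, c(n, n, length(times)))
  for (i in seq_along(times)) K[, , i][rad <= 0.4 * times[i]] <- 1
  snaps <- list(times = times, K = K)
  v <- propagation_speed(snaps, origin = c(30, 30), direction = c(0, 1),
                         dx = 1)
  expect_equal(as.numeric(v), 0.4, tolerance = 0.05)
  expect_error(propagation_speed(snaps, origin = c(30, 30),
                                 direction = c(0, 1), dx = 1,
                                 time_range = c(0, 5)),
               "speed undefined")
})

test_that("wavefront speed is isotropic in the homogeneous preset", {
  run <- run_homogeneous()
  ctr <- c(40.5, 40.5)
  dirs <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  v <- vapply(dirs, function(d) {
    as.numeric(propagation_speed(run, origin = ctr, direction = d,
                                 time_range = c(100, 500)))
  }, numeric(1))
  expect_lt(diff(range(v)) / mean(v), 0.01)
})

test_that("re-entry detection counts events against delivered stimuli", {
  run <- run_homogeneous()
  re <- detect_reentry(run)
  expect_false(re$reentry)
  expect_equal(re$extra_waves, 0)
  re2 <- detect_reentry(run, n_stimuli = 0)   # pretend nothing was delivered
  expect_true(re2$reentry)
  expect_equal(re2$extra_waves, 1)
})

test_that("sweep_F input checks and the F = 1 control case", {
  expect_error(sweep_F("bypass", c(0.5, 0.2)))       # unsorted
  expect_error(sweep_F("bypass", c(0, 0.5)))         # F = 0 excluded
  sw <- cached("sweep_f1", sweep_F("bypass", 1))
  expect_equal(sw$regime, "homogeneous")
  b <- sweep_boundaries(sw)
  expect_true(is.na(b["largest_blocked"]))
})
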