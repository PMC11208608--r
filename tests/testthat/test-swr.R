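test_that("embedded sharp waves are recovered at the right times", {
  fx <- fixture_lfp(n_events = 20, duration = 60, fs = 2000, seed = 42)
  ev <- detect_swr(fx$recording, threshold_sd = 3)
  expect_identical(nrow(ev), 20L)
  err <- vapply(fx$truth$peak_time,
                function(tt) min(abs(ev$peak_time - tt)), numeric(1))
  expect_lt(max(err), 0.010)
  # amplitude recovered within 10% of the generative 160 uV
  expect_lt(abs(mean(ev$swr_amplitude) - 160) / 160, 0.10)
  # boundaries bracket the peaks
  expect_true(all(ev$onset <= ev$peak_time & ev$peak_time <= ev$offset))
})

test_that("pure noise produces no events at high threshold and the detector is monotone in threshold", {
  noise <- simulate_lfp(duration = 30, fs = 2000, swr_amplitude = 0,
                        ripple_amplitude = 0, event_rate = 0, seed = 7)
  expect_identical(nrow(detect_swr(noise$recording, threshold_sd = 10)), 0L)

  fx <- fixture_lfp(n_events = 10, duration = 30, seed = 3)
  counts <- vapply(c(2, 2.5, 3, 4, 6, 9),
                   function(th) nrow(detect_swr(fx$recording,
                                                threshold_sd = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("SWR prevalence follows the 2 SD criterion", {
  pos <- fixture_lfp(n_events = 15, duration = 40, seed = 5)
  neg <- simulate_lfp(duration = 40, fs = 2000, swr_amplitude = 0,
                      ripple_amplitude = 0, event_rate = 0,
                      noise_color = "white", seed = 6)
  ev_pos <- detect_swr(pos$recording)
  ev_neg <- detect_swr(neg$recording)
  expect_identical(summarize_swr(ev_pos, pos$recording)$prevalence,
                   "positive")
  expect_identical(summarize_swr(ev_neg, neg$recording)$prevalence,
                   "negative")
})

test_that("detector accepts the opposite sharp-wave polarity", {
  fx <- fixture_lfp(n_events = 8, duration = 25, seed = 9,
                    polarity = "positive")
  ev <- detect_swr(fx$recording, polarity = "positive")
  expect_identical(nrow(ev), 8L)
})

test_that("ripple metrics recover the generative ripple frequency", {
  fx <- fixture_lfp(n_events = 20, duration = 60, fs = 2000, seed = 42)
  ev <- detect_swr(fx$recording)
  rm <- ripple_metrics(fx$recording, ev)
  expect_true(all(abs(rm$ripple_frequency - 200) <= 5, na.rm = TRUE))
  expect_true(all(is.na(rm$ripple_trigger_time) |
                    (rm$ripple_trigger_time >= rm$onset &
                       rm$ripple_trigger_time <= rm$offset)))
  # default band bounds
  expect_identical(eval(formals(ripple_metrics)$band), c(170, 230))
})

test_that("events without ripple content get undefined ripple fields", {
  fx <- fixture_lfp(n_events = 6, duration = 20, fs = 2000,
                    ripple_amplitude = 0, seed = 13)
  ev <- detect_swr(fx$recording)
  rm <- ripple_metrics(fx$recording, ev)
  expect_true(all(is.na(rm$ripple_frequency)))
  expect_identical(nrow(rm), nrow(ev))   # events retained
})

test_that("triggered averages align waveforms and suppress noise", {
  fs <- 1000
  n <- 20000
  x <- numeric(n)
  w <- exp(-((-50:50) / 15)^2)           # one waveform copied at triggers
  trig_idx <- seq(500, n - 500, by = 400)
  for (k in trig_idx) x[(k - 50):(k + 50)] <- w
  rec <- lfp_recording(x, fs)
  ta <- triggered_average(rec, (trig_idx - 1) / fs, window = 0.05)
  expect_equal(ta$average, w, tolerance = 1e-12)
  expect_identical(ta$n_used, length(trig_idx))

  # triggers at the negative peaks of a 200 Hz sine: phase-locked average
  t <- (seq_len(4000) - 1) / 2000
  s <- sin(2 * pi * 200 * t)
  rec2 <- lfp_recording(s, 2000)
  neg <- seq(3 / (4 * 200), max(t) - 0.025, by = 1 / 200)
  ta2 <- triggered_average(rec2, neg, window = 0.02)
  centre <- (length(ta2$average) + 1) / 2
  # the centre sits at the (periodic) minimum: the negative peak is
  # preserved at zero lag in the phase-locked average
  expect_equal(ta2$average[centre], min(ta2$average), tolerance = 1e-9)

  # residual noise SD shrinks roughly as 1/sqrt(N) with N = 50 copies
  set.seed(1)
  n2 <- 60000
  xn <- rnorm(n2)
  trig2 <- seq(600, n2 - 600, length.out = 50)
  rec3 <- lfp_recording(xn, fs)
  ta3 <- triggered_average(rec3, (round(trig2) - 1) / fs, window = 0.05)
  expect_equal(sd(ta3$average), 1 / sqrt(50), tolerance = 0.20)

  # all triggers at the edges is an error
  expect_error(triggered_average(rec, 0.0001, window = 0.05), "edges")
})

test_that("select_top_window matches the exhaustive optimum", {
  # small worked example: amplitudes 1,1,9,9,9,1 with n = 3
  ev <- tibble::tibble(peak_time = 1:6,
                       swr_amplitude = c(1, 1, 9, 9, 9, 1))
  expect_identical(select_top_window(ev, n = 3)$peak_time, 3:5)

  # fewer events than the window: all returned; default n is 100
  expect_identical(nrow(select_top_window(ev[1:5, ])), 5L)
  expect_identical(formals(select_top_window)$n, 100)

  # brute force over random event lists
  set.seed(10)
  for (trial in 1:100) {
    m <- sample(5:500, 1)
    n <- sample(2:10, 1)
    amps <- rexp(m)
    evr <- tibble::tibble(peak_time = seq_len(m), swr_amplitude = amps)
    got <- select_top_window(evr, n = n)
    if (m <= n) {
      expect_identical(nrow(got), m)
    } else {
      best <- max(vapply(seq_len(m - n + 1),
                         function(s) mean(amps[s:(s + n - 1)]), numeric(1)))
      expect_equal(mean(got$swr_amplitude), best)
    }
  }
})

test_that("summaries report intervals and handle the empty case", {
  rec <- fixture_lfp(n_events = 5, duration = 20, seed = 2)$recording
  ev <- tibble::tibble(peak_time = c(1.0, 1.5),
                       swr_amplitude = c(100, 110))
  s <- summarize_swr(ev, rec)
  expect_equal(s$mean_interval, 0.5)
  expect_identical(s$n_events, 2L)

  s0 <- summarize_swr(ev[0, ], rec)
  expect_identical(s0$n_events, 0L)
  expect_true(is.na(s0$mean_interval))
})
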