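test_that("a triangular spike satisfying both thresholds is the only regrip", {
  n <- 600
  # base 5 mm, apex 6 mm, 10 ms flanks -> slope 100 mm/s on both flanks
  D <- triangle_pulse_trace(n, base = 5, apex_frame = 300, height = 1,
                            flank = 0.01)
  ev <- detect_regrips(D, FPS)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$peak_frame, 299L)
  # below-prominence pulse: no events
  small <- triangle_pulse_trace(n, base = 5, apex_frame = 300, height = 0.5,
                                flank = 0.001)
  expect_equal(nrow(detect_regrips(small, FPS)), 0L)
  # smooth 1 mm bump over 2 s: prominence passes, slope filter rejects
  slow <- gaussian_pulse_trace(n, base = 5, times = 1, height = 1,
                               sigma = 0.35)
  expect_equal(nrow(detect_regrips(slow, FPS)), 0L)
})

test_that("slope rule 'both' requires both flanks; 'either' accepts one", {
  n <- 800
  t <- (seq_len(n) - 1) / FPS
  # sharp rise (10 ms), slow fall (500 ms)
  apex <- 1.0
  D <- 5 + ifelse(t < apex, pmax(0, 1 - (apex - t) / 0.01),
                  pmax(0, 1 - (t - apex) / 0.5))
  expect_equal(nrow(detect_regrips(D, FPS)), 0L)
  p_either <- detection_params(regrip_slope_rule = "either")
  expect_equal(nrow(detect_regrips(D, FPS, p_either)), 1L)
})

test_that("detection and amplitude are invariant to adding a constant", {
  set.seed(51)
  D <- gaussian_pulse_trace(3000, base = 5, times = c(2, 5, 8),
                            height = 1.5, sigma = 0.0072) + rnorm(3000, 0, 0.01)
  a <- peak_metrics(D, detect_regrips(D, FPS), FPS)
  b <- peak_metrics(D + 7, detect_regrips(D + 7, FPS), FPS)
  expect_equal(b$peak_frame, a$peak_frame)
  expect_equal(b$amplitude, a$amplitude, tolerance = 1e-9)
  expect_equal(b$fwhm, a$fwhm, tolerance = 1e-9)
})

test_that("every returned regrip satisfies the enabled thresholds", {
  s <- generate_session(generator_params(duration = 30), seed = 3)
  f <- compute_features(calibrate(s$front, s$truth$calibration))
  ev <- detect_regrips(f)
  expect_gt(nrow(ev), 10L)
  expect_true(all(ev$prominence >= 0.75))
  for (i in seq_len(nrow(ev))) {
    sl <- handkin:::flank_slopes(f$D, FPS, ev$peak_frame[i] + 1L,
                                 ev$left_base[i] + 1L, ev$right_base[i] + 1L)
    expect_gt(min(sl), 88)
  }
})

test_that("ethogram filtering keeps only oromanual-phase regrips", {
  n <- 2000
  D <- gaussian_pulse_trace(n, base = 5, times = c(1, 4), height = 1.5,
                            sigma = 0.0072)
  # oromanual covers t in [0.5, 2); the t = 4 pulse falls in holding
  eth <- ethogram(c(0, round(0.5 * FPS), round(2 * FPS)), c("H", "O", "H"), n)
  ev <- detect_regrips(D, FPS, eth = eth)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$peak_time, 1, tolerance = 2 / FPS)
})

test_that("sniff detection applies depth, prominence and separation rules", {
  n <- 3000
  # one dip to 2.0 mm: detected at the dip minimum
  L <- gaussian_pulse_trace(n, base = 5, times = 3, height = -3, sigma = 0.034)
  ev <- detect_sniffs(L, FPS)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$peak_time, 3, tolerance = 2 / FPS)
  expect_equal(ev$peak_value, 2, tolerance = 0.01) # dip minimum off-grid
  # dip to 3.0 mm misses the 2.5 mm depth criterion
  shallow <- gaussian_pulse_trace(n, base = 5, times = 3, height = -2,
                                  sigma = 0.034)
  expect_equal(nrow(detect_sniffs(shallow, FPS)), 0L)
})

test_that("separation conflicts keep the more prominent dip", {
  n <- 3000
  t <- (seq_len(n) - 1) / FPS
  # two dips 100 ms apart with prominences 3.0 and 2.8 mm
  L <- 5 - 3.0 * exp(-(t - 3)^2 / (2 * 0.012^2)) -
    2.8 * exp(-(t - 3.1)^2 / (2 * 0.012^2))
  ev <- detect_sniffs(L, FPS)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$peak_time, 3, tolerance = 2 / FPS)
})

test_that("head-fixed mode raises prominence and caps width", {
  n <- 6000
  # 2 mm-prominence dip passes freely-moving, fails head-fixed
  L <- gaussian_pulse_trace(n, base = 4, times = 3, height = -2, sigma = 0.034)
  expect_equal(nrow(detect_sniffs(L, FPS)), 1L)
  expect_equal(nrow(detect_sniffs(L, FPS, mode = "head_fixed")), 0L)
  # deep but slow dip (sigma 400 ms -> half-prominence width ~940 ms)
  wide <- gaussian_pulse_trace(n, base = 6, times = 10, height = -4,
                               sigma = 0.4)
  expect_equal(nrow(detect_sniffs(wide, FPS, mode = "head_fixed")), 0L)
  sharp <- gaussian_pulse_trace(n, base = 6, times = 10, height = -4,
                                sigma = 0.034)
  expect_equal(nrow(detect_sniffs(sharp, FPS, mode = "head_fixed")), 1L)
})

test_that("peak metrics reproduce the worked ramp + pulse fixture", {
  n <- round(FPS) # 1 s
  t <- (seq_len(n) - 1) / FPS
  apex_frame <- round(0.5 * FPS) # pulse apex on the sampling grid
  ta <- (apex_frame - 1) / FPS
  D <- 4.9 + 0.2 * t + pmax(0, 1 - abs(t - ta) / 0.01)
  ev <- detect_regrips(D, FPS)
  expect_equal(nrow(ev), 1L)
  m <- peak_metrics(D, ev, FPS)
  expect_true(m$valid)
  expect_equal(m$baseline_value, 4.9 + 0.2 * ta, tolerance = 1e-3)
  expect_equal(m$amplitude, 1.0, tolerance = 2e-3)
  expect_equal(m$fwhm, 0.010, tolerance = 1.5 / FPS)
})

test_that("Gaussian pulse FWHM equals 2.3548 sigma within a frame", {
  for (sigma in c(0.0072, 0.034)) {
    n <- 3000
    x <- gaussian_pulse_trace(n, base = 5, times = 5, height = 2,
                              sigma = sigma)
    ev <- detect_regrips(x, FPS,
                         detection_params(regrip_min_slope = 0))
    m <- peak_metrics(x, ev, FPS)
    expect_lt(abs(m$fwhm - 2 * sqrt(2 * log(2)) * sigma), 1 / FPS)
  }
})

test_that("events whose baseline windows leave the trace are flagged invalid", {
  D <- triangle_pulse_trace(200, base = 5, apex_frame = 6, height = 1,
                            flank = 0.005)
  ev <- detect_regrips(D, FPS)
  expect_equal(nrow(ev), 1L)
  m <- peak_metrics(D, ev, FPS)
  expect_false(m$valid)
  expect_true(is.na(m$amplitude))
})

test_that("peak-aligned averaging centers snippets and tolerates edges", {
  n <- 4000
  # pulse centers on the sampling grid so the two snippets are identical
  D <- gaussian_pulse_trace(n, base = 5, times = c(882, 2646) / FPS,
                            height = 1.5, sigma = 0.0072)
  ev <- detect_regrips(D, FPS)
  av <- align_and_average(D, ev, FPS, half_window = 0.05)
  expect_equal(nrow(av$snippets), 2L)
  # two identical pulses: the mean equals either snippet
  expect_equal(av$mean, av$snippets[1, ], tolerance = 1e-9)
  # mean peak sits at zero lag
  expect_equal(av$lag[which.max(av$mean)], 0, tolerance = 1.5 / FPS)
  # event at the very first frame: leading lags missing, mean still defined
  ev_edge <- ev[1, ]; ev_edge$peak_frame <- 0L; ev_edge$peak_time <- 0
  av2 <- align_and_average(D, ev_edge, FPS, half_window = 0.05)
  expect_true(anyNA(av2$snippets[1, ]))
  expect_false(anyNA(av2$mean[av$lag >= 0]))
})

test_that("maneuver rates and phase-relative latencies follow the ethogram", {
  fps <- 100
  eth <- ethogram(c(0, 100, 200, 300, 400), c("O", "H", "O", "H", "O"), 500)
  ev <- data.frame(kind = "sniff", peak_frame = c(190L, 150L, 250L, 390L),
                   peak_time = c(1.90, 1.50, 2.50, 3.90))
  out <- maneuver_rates_and_timing(ev, eth, fps, total_time = 2)
  expect_equal(out$rate, 2)
  # sniff 100 ms before the next oromanual onset
  expect_equal(out$latency_next[1], 0.10, tolerance = 1e-9)
  expect_equal(out$latency_prev[1], 0.90, tolerance = 1e-9)
  # event in an oromanual phase: no latencies
  expect_true(is.na(out$latency_next[3]))
  expect_error(maneuver_rates_and_timing(ev, eth, fps, total_time = 0),
               class = "handkin_parameter_error")
})

test_that("sniffs in an edge holding segment get no latency across the cut", {
  fps <- 100
  eth <- ethogram(c(0, 100, 200), c("O", "H", "O"), 300)
  # last segment is oromanual here; make a final-holding case instead
  eth2 <- ethogram(c(0, 100), c("O", "H"), 300)
  ev <- data.frame(kind = "sniff", peak_frame = 250L, peak_time = 2.5)
  out <- maneuver_rates_and_timing(ev, eth2, fps, total_time = 3)
  expect_true(is.na(out$latency_next))
  expect_equal(out$latency_prev, 1.5, tolerance = 1e-9)
})
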