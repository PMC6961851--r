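test_that("phase statistics match a hand count on a five-segment ethogram", {
  fps <- 100
  # H 0.3 s, O 0.2 s, H 0.3 s, O 0.2 s, H 0.5 s  (total 1.5 s)
  eth <- ethogram(c(0, 30, 50, 80, 100), c("H", "O", "H", "O", "H"), 150)
  ps <- phase_statistics(eth, fps)
  expect_equal(ps$switch_rate, 4 / 1.5)
  expect_equal(ps$duty_cycle, 0.4 / 1.5)
  # durations use only the three interior segments
  expect_equal(sort(ps$phase_durations$oromanual), c(0.2, 0.2))
  expect_equal(ps$phase_durations$holding, 0.3)
})

test_that("single-segment ethograms yield zero switches, no interior durations", {
  ps <- phase_statistics(ethogram(0, "H", 100), 100)
  expect_equal(ps$switch_rate, 0)
  expect_length(ps$phase_durations$holding, 0)
  expect_length(ps$phase_durations$oromanual, 0)
})

test_that("strict equal alternation gives a 0.5 duty cycle", {
  fps <- 100
  starts <- seq(0, 975, by = 25)
  eth <- ethogram(starts, rep(c("H", "O"), 20), 1000)
  ps <- phase_statistics(eth, fps)
  expect_equal(ps$duty_cycle, 0.5)
  expect_equal(ps$switch_rate, 39 / 10)
})

# independent brute-force of the two-line knee criterion
lmethod_oracle <- function(sse) {
  kmax <- length(sse)
  cand <- 2:(kmax - 1)
  err <- sapply(cand, function(cc) {
    i1 <- 1:cc; i2 <- cc:kmax
    r1 <- sqrt(mean(resid(lm(sse[i1] ~ i1))^2))
    r2 <- sqrt(mean(resid(lm(sse[i2] ~ i2))^2))
    (length(i1) * r1 + length(i2) * r2) / (length(i1) + length(i2))
  })
  cand[which(err <= min(err) + 1e-9 * max(1, abs(min(err))))[1]]
}

test_that("L-method knee selection matches the brute-force oracle", {
  curve2 <- c(100, 10, 9.5, 9.2, 9.0, 8.9, 8.8, 8.7, 8.6, 8.5)
  expect_equal(select_k_lmethod(curve2), 2L)
  expect_equal(select_k_lmethod(curve2), lmethod_oracle(curve2))

  # elbow fabricated at k = 3: steep to 3, flat after
  curve3 <- c(200, 80, 8, 7.6, 7.3, 7.1, 7.0, 6.9)
  expect_equal(select_k_lmethod(curve3), 3L)
  expect_equal(select_k_lmethod(curve3), lmethod_oracle(curve3))

  # randomized knees against the oracle
  set.seed(21)
  for (rep in 1:10) {
    knee <- sample(2:8, 1)
    sse <- c(seq(100, 20, length.out = knee),
             seq(19, 15, length.out = 10 - knee)) + runif(10, 0, 0.3)
    sse <- rev(cummax(rev(sse))) # keep non-increasing
    expect_equal(select_k_lmethod(sse), lmethod_oracle(sse))
  }
})

test_that("a perfectly linear SSE curve ties and breaks to the smallest c", {
  expect_equal(select_k_lmethod(seq(100, 10, length.out = 10)), 2L)
  expect_error(select_k_lmethod(c(3, 2, 1)), class = "handkin_parameter_error")
})

test_that("two-blob (L, D) data recover k = 2 and the generating centroids", {
  set.seed(31)
  n <- 500
  pts <- data.frame(
    L = c(rnorm(n, 5.1, 0.3), rnorm(n, 2.7, 0.3)),
    D = c(rnorm(n, 4.0, 0.3), rnorm(n, 6.0, 0.3)))
  cl <- cluster_phases(pts, rng_seed = 99)
  expect_equal(cl$k_selected, 2L)
  cent <- cl$centroids[order(cl$centroids[, "L"]), ]
  expect_lt(max(abs(cent[1, ] - c(2.7, 6.0))), 0.1)
  expect_lt(max(abs(cent[2, ] - c(5.1, 4.0))), 0.1)
  # the small-L cluster is the oromanual mode
  oro <- which(cl$phase_labels == "oromanual")
  expect_equal(unname(cl$centroids[oro, "L"]), cent[1, "L"], ignore_attr = TRUE)
  # SSE curve is non-increasing and every non-missing sample is assigned
  expect_true(all(diff(cl$sse_curve) <= 1e-6))
  expect_false(anyNA(cl$assignments))
})

test_that("identical samples are degenerate and force k = 1", {
  pts <- data.frame(L = rep(3, 50), D = rep(4, 50))
  cl <- cluster_phases(pts, rng_seed = 1)
  expect_true(cl$degenerate)
  expect_equal(cl$k_selected, 1L)
  expect_equal(cl$sse_curve, rep(0, 10))
})

test_that("cluster assignments agree with the generating state sequence", {
  s <- generate_session(generator_params(duration = 40), seed = 5)
  f <- compute_features(calibrate(s$front, s$truth$calibration))
  cl <- cluster_phases(f, rng_seed = 7)
  expect_equal(cl$k_selected, 2L)
  truth_phase <- phase_per_frame(s$truth$ethogram)
  pred <- cl$phase_labels[cl$assignments]
  ok <- !is.na(pred) & !is.na(truth_phase)
  expect_gt(mean(pred[ok] == truth_phase[ok]), 0.9)
})

test_that("density maps are max-normalized with a circular 10% contour", {
  set.seed(41)
  pts <- data.frame(L = rnorm(2000, 10, 1), D = rnorm(2000, 10, 1))
  dm <- density_contours(list(a = pts, b = pts + 0.1), grid_n = 128)
  for (m in dm$maps) expect_equal(max(m$z), 1)
  # 10%-of-peak radius of the kernel-smoothed Gaussian (closed form):
  # smoothed sd^2 = data sd^2 + kernel sd^2, radius = sd * sqrt(2 ln 10)
  m <- dm$maps[[1]]
  h <- MASS::bandwidth.nrd(pts$L) / 4
  r_expect <- sqrt(1 + h^2) * sqrt(2 * log(10))
  cont <- m$contour[[1]]
  r_obs <- sqrt((cont$x - mean(cont$x))^2 + (cont$y - mean(cont$y))^2)
  expect_lt(abs(mean(r_obs) - r_expect) / r_expect, 0.1)
  expect_lt((max(r_obs) - min(r_obs)) / mean(r_obs), 0.25) # near-circular
  # a tight cluster's maximum sits at the cluster center
  tight <- data.frame(L = rnorm(200, 5, 0.2), D = rnorm(200, 12, 0.2))
  dmt <- density_contours(list(tight), grid_n = 128)
  mx <- which(dmt$maps[[1]]$z == 1, arr.ind = TRUE)
  expect_lt(abs(dmt$maps[[1]]$x[mx[1]] - 5), 0.5)
  expect_lt(abs(dmt$maps[[1]]$y[mx[2]] - 12), 0.5)
})

test_that("rise time recovers a pure ramp's onset exactly", {
  fps <- 1000
  t <- seq(0, 2, by = 1 / fps)
  # constant 5 until t = 1.9, then linear to 3 at t = 2.0
  L <- ifelse(t < 1.9, 5, 5 - 20 * (t - 1.9))
  expect_equal(transition_rise_time(L, fps, 2.0), 0.1, tolerance = 1e-9)
  # translation invariance
  expect_equal(transition_rise_time(L + 3, fps, 2.0), 0.1, tolerance = 1e-9)

  # arbitrary slopes and baselines, at the analysis frame rate
  fps <- FPS
  t2 <- seq(0, 1.5, by = 1 / fps)
  for (ramp_dur in c(0.05, 0.12, 0.3)) {
    for (base in c(5, 2.3)) {
      L2 <- ifelse(t2 < 1.2 - ramp_dur, base,
                   base - 2 * (t2 - (1.2 - ramp_dur)) / ramp_dur)
      got <- transition_rise_time(L2, fps, 1.2)
      expect_lt(abs(got - ramp_dur), 1 / fps)
    }
  }
})

test_that("degenerate transitions signal an undefined result", {
  fps <- 294.1
  t <- seq(0, 1.5, by = 1 / fps)
  flat <- rep(5, length(t))
  expect_warning(out <- transition_rise_time(flat, fps, 1.2),
                 class = "handkin_undefined_result")
  expect_true(is.na(out))
  # step exactly at the transition frame: crossings collapse into one frame
  fps2 <- 100
  t3 <- seq(0, 1.5, by = 1 / fps2)
  step <- ifelse(t3 < 1.2, 5, 3)
  out2 <- transition_rise_time(step, fps2, 1.2)
  expect_lte(out2, 1 / fps2 + 1e-9)
  expect_error(transition_rise_time(flat, fps, 0.5),
               class = "handkin_parameter_error")
})
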