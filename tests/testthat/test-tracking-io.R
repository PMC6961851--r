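test_that("a well-formed tracking table parses to the identity trajectory", {
  path <- withr::local_tempfile(fileext = ".csv")
  parts_row <- rep(c("nose", "LD3", "RD3"), each = 3L)
  coords_row <- rep(c("x", "y", "likelihood"), 3L)
  data <- rbind(c(1, 2, 1, 3, 4, 1, 5, 6, 1),
                c(1.5, 2.5, 1, 3.5, 4.5, 1, 5.5, 6.5, 1))
  write_dlc_csv(path, parts_row, coords_row, data)
  tr <- read_tracking_table(path, view = "front")
  expect_s3_class(tr, "tracked_trajectory")
  expect_equal(nrow(tr$x), 2L)
  expect_equal(tr$bodyparts, c("nose", "LD3", "RD3"))
  expect_false(any(tr$mask))
  expect_equal(unname(tr$x[, "LD3"]), c(3, 3.5))
  expect_equal(unname(tr$y[, "RD3"]), c(6, 6.5))
  expect_identical(tr$units, "px")
})

test_that("column order does not matter: permuted tables parse identically", {
  ref <- withr::local_tempfile(fileext = ".csv")
  perm <- withr::local_tempfile(fileext = ".csv")
  parts_row <- rep(c("nose", "LD3"), each = 3L)
  coords_row <- rep(c("x", "y", "likelihood"), 2L)
  data <- rbind(c(1, 2, 0.9, 3, 4, 0.8),
                c(5, 6, 0.7, 7, 8, 0.6))
  write_dlc_csv(ref, parts_row, coords_row, data)
  ord <- c(4, 6, 1, 3, 5, 2) # scramble columns
  write_dlc_csv(perm, parts_row[ord], coords_row[ord], data[, ord])
  a <- read_tracking_table(ref)
  b <- read_tracking_table(perm)
  for (p in a$bodyparts) {
    expect_equal(b$x[, p], a$x[, p])
    expect_equal(b$y[, p], a$y[, p])
    expect_equal(b$likelihood[, p], a$likelihood[, p])
  }
})

test_that("format errors name the offending part / row", {
  path <- withr::local_tempfile(fileext = ".csv")
  # RD3 missing its likelihood column
  parts_row <- c(rep("nose", 3L), "RD3", "RD3")
  coords_row <- c("x", "y", "likelihood", "x", "y")
  write_dlc_csv(path, parts_row, coords_row,
                rbind(c(1, 2, 1, 3, 4), c(1, 2, 1, 3, 4)))
  expect_error(read_tracking_table(path), "RD3", class = "handkin_format_error")

  path2 <- withr::local_tempfile(fileext = ".csv")
  parts_row <- rep("nose", 3L)
  coords_row <- c("x", "y", "likelihood")
  write_dlc_csv(path2, parts_row, coords_row,
                rbind(c(1, 2, 1), c(1, "oops", 1)))
  expect_error(read_tracking_table(path2), "row 2",
               class = "handkin_parse_error")

  expect_error(
    tracked_trajectory(matrix(1, 2, 2), matrix(1, 2, 2), matrix(1, 2, 2),
                       bodyparts = c("nose", "nose")),
    "duplicate", class = "handkin_format_error")
  expect_error(read_tracking_table("whatever.h5"),
               class = "handkin_format_error")
})

test_that("tracking write/read round-trips to numeric identity", {
  set.seed(7)
  x <- matrix(runif(30, 0, 512), 10, 3,
              dimnames = list(NULL, c("nose", "LD3", "RD3")))
  y <- matrix(runif(30, 0, 512), 10, 3, dimnames = dimnames(x))
  lik <- matrix(runif(30), 10, 3, dimnames = dimnames(x))
  tr <- make_traj(x, y, lik, units = "px")
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking_table(tr, path)
  tr2 <- read_tracking_table(path)
  expect_equal(tr2$x, tr$x)
  expect_equal(tr2$y, tr$y)
  expect_equal(tr2$likelihood, tr$likelihood)
})

test_that("likelihood masking counts thresholded samples exactly", {
  lik <- matrix(1, 5, 2)
  lik[c(2, 7, 9)] <- 0.5
  tr <- make_traj(matrix(1, 5, 2, dimnames = list(NULL, c("a", "b"))),
                  matrix(1, 5, 2), lik, units = "px")
  expect_identical(mask_low_quality(tr, 0), tr) # floor 0 is the identity
  m <- mask_low_quality(tr, 0.9)
  expect_equal(sum(m$mask), 3L)
  expect_equal(m$x, tr$x) # original values retained under the mask
  expect_error(mask_low_quality(tr, 1.5), class = "handkin_parameter_error")
})

test_that("interval masking hits exactly the half-open frame range", {
  tr <- const_traj(list(a = c(0, 0), b = c(1, 1)), n_frames = 30,
                   units = "px")
  m <- mask_low_quality(tr, exclusion_intervals = cbind(10, 20))
  expect_true(all(m$mask[11:20, ]))
  expect_false(any(m$mask[c(1:10, 21:30), ]))
})

test_that("masking is idempotent and order-independent", {
  set.seed(1)
  lik <- matrix(runif(40), 20, 2)
  tr <- make_traj(matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b"))),
                  matrix(rnorm(40), 20, 2), lik, units = "px")
  iv <- cbind(c(0, 15), c(5, 18))
  ab <- mask_low_quality(mask_low_quality(tr, 0.5), exclusion_intervals = iv)
  ba <- mask_low_quality(mask_low_quality(tr, exclusion_intervals = iv), 0.5)
  twice <- mask_low_quality(ab, 0.5, iv)
  expect_equal(ab$mask, ba$mask)
  expect_equal(twice$mask, ab$mask)
})

test_that("calibration scales positions, sets mm state, and refuses to repeat", {
  tr <- const_traj(list(p = c(100, 50)), n_frames = 295, units = "px")
  cal <- calibrate(tr, 0.05)
  expect_equal(unname(cal$x[1, "p"]), 5)
  expect_equal(unname(cal$y[1, "p"]), 2.5)
  expect_identical(cal$units, "mm")
  expect_error(calibrate(cal, 0.05), class = "handkin_state_error")
  # identity scale leaves numbers unchanged
  expect_equal(calibrate(tr, 1)$x, tr$x)
  # frame i is at i / fps seconds
  expect_equal(frame_times(cal)[295], 294 / 294.1, tolerance = 1e-12)
})

test_that("ethograms build half-open alternating segments with edge flags", {
  eth <- ethogram(c(0, 100, 150), c("H", "O", "H"), 300)
  expect_equal(eth$start, c(0L, 100L, 150L))
  expect_equal(eth$end, c(100L, 150L, 300L))
  expect_equal(eth$phase, c("holding", "oromanual", "holding"))
  expect_equal(eth$interior, c(FALSE, TRUE, FALSE))

  single <- ethogram(0, "H", 50)
  expect_equal(nrow(single), 1L)
  expect_false(single$interior)

  expect_error(ethogram(c(0, 10), c("H", "H"), 50),
               class = "handkin_validation_error")
  expect_error(ethogram(c(0, 60), c("H", "O"), 50),
               class = "handkin_range_error")
  expect_error(ethogram(c(10, 5), c("H", "O"), 50),
               class = "handkin_validation_error")
})

test_that("ethogram file round-trip is the identity, grips default to absent", {
  eth <- ethogram(c(0, 40, 90, 130), c("H", "O", "H", "O"), 200,
                  grip_left = c("thumb_hold", "absent", "pincer", "absent"),
                  grip_right = c("thumb_hold", "absent", "indeterminate", "absent"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ethogram(eth, path)
  back <- read_ethogram(path, 200)
  expect_equal(as.data.frame(back), as.data.frame(eth))

  # a minimal file without grip columns
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("frame,phase", "0,H", "100,O"), path2)
  e2 <- read_ethogram(path2, 300)
  expect_equal(e2$grip_left, c("absent", "absent"))
})
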