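# fixtures built in code, shared across test files

FPS <- 294.1

# trajectory with parts at fixed positions (frames x parts matrices)
make_traj <- function(x, y, likelihood = NULL, parts = colnames(x),
                      view = "front", units = "mm", fps = FPS) {
  if (is.null(likelihood)) likelihood <- matrix(1, nrow(x), ncol(x))
  tracked_trajectory(x, y, likelihood, bodyparts = parts, view = view,
                     fps = fps, units = units,
                     mm_per_px = if (units == "mm") 1 else "uncalibrated")
}

# constant-position trajectory: positions is a named list of c(x, y)
const_traj <- function(positions, n_frames = 10, ...) {
  parts <- names(positions)
  x <- sapply(positions, `[`, 1L)
  y <- sapply(positions, `[`, 2L)
  make_traj(matrix(x, n_frames, length(parts), byrow = TRUE,
                   dimnames = list(NULL, parts)),
            matrix(y, n_frames, length(parts), byrow = TRUE,
                   dimnames = list(NULL, parts)), ...)
}

# flat trace with a triangular pulse: flank duration in s, apex at a frame
triangle_pulse_trace <- function(n, fps = FPS, base = 5, apex_frame,
                                 height = 1, flank = 0.01) {
  t <- (seq_len(n) - 1L) / fps
  ta <- (apex_frame - 1L) / fps
  pulse <- pmax(0, 1 - abs(t - ta) / flank) * height
  base + pulse
}

# flat trace with Gaussian pulses (signed height) at given times
gaussian_pulse_trace <- function(n, fps = FPS, base = 5, times, height,
                                 sigma) {
  t <- (seq_len(n) - 1L) / fps
  x <- rep(base, n)
  for (tt in times) x <- x + height * exp(-(t - tt)^2 / (2 * sigma^2))
  x
}

# DLC-dialect CSV written by hand (columns in the given order)
write_dlc_csv <- function(path, parts_row, coords_row, data_rows) {
  lines <- c(paste(c("scorer", rep("s", length(parts_row))), collapse = ","),
             paste(c("bodyparts", parts_row), collapse = ","),
             paste(c("coords", coords_row), collapse = ","),
             vapply(seq_len(nrow(data_rows)), function(i) {
               paste(c(i - 1L, data_rows[i, ]), collapse = ",")
             }, ""))
  writeLines(lines, path)
  path
}
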