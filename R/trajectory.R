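#' Tracked body-part trajectory for one camera view
#'
#' Container for per-frame 2D positions and tracking confidence of named body
#' parts, as exported by markerless pose-estimation software. Positions use
#' image conventions: x grows rightward, y grows downward. Frames are 0-based
#' and contiguous. The unit state is explicit: trajectories start out in
#' pixels (`units = "px"`, `mm_per_px = "uncalibrated"`) and switch to
#' millimetres only through [calibrate()].
#'
#' @param x,y,likelihood numeric matrices, frames x body parts.
#' @param bodyparts character vector of unique body-part names (one per
#'   column).
#' @param view one of `"front"`, `"side"`, `"ventral"`.
#' @param fps frames per second (default 294.1, the acquisition rate the
#'   pipeline was designed around).
#' @param units `"px"` or `"mm"`.
#' @param mm_per_px positive scale factor, or `"uncalibrated"`.
#' @param mask logical matrix, frames x parts; `TRUE` marks a sample excluded
#'   from analysis. Original values are retained under the mask.
#' @return An object of class `tracked_trajectory`.
#' @seealso [read_tracking_table()], [calibrate()], [mask_low_quality()]
#' @export
tracked_trajectory <- function(x, y, likelihood, bodyparts,
                               view = c("front", "side", "ventral"),
                               fps = 294.1, units = "px",
                               mm_per_px = "uncalibrated",
                               mask = NULL) {
  view <- match.arg(view)
  x <- as.matrix(x); y <- as.matrix(y); likelihood <- as.matrix(likelihood)
  if (anyDuplicated(bodyparts)) {
    stop_handkin(sprintf("duplicate body-part name: %s",
                         bodyparts[duplicated(bodyparts)][1L]),
                 "handkin_format_error")
  }
  if (ncol(x) != length(bodyparts) || !all(dim(x) == dim(y)) ||
      !all(dim(x) == dim(likelihood))) {
    stop_handkin("x, y, likelihood must be frames x bodyparts matrices of equal shape",
                 "handkin_format_error")
  }
  if (nrow(x) < 1L) stop_handkin("at least one frame required", "handkin_format_error")
  lk <- likelihood[!is.na(likelihood)]
  if (length(lk) && (min(lk) < 0 || max(lk) > 1)) {
    stop_handkin("likelihood values must lie in [0, 1]", "handkin_format_error")
  }
  if (is.null(mask)) mask <- matrix(FALSE, nrow(x), ncol(x))
  mask <- mask | is.na(x) | is.na(y)
  colnames(x) <- colnames(y) <- colnames(likelihood) <- colnames(mask) <- bodyparts
  structure(list(view = view, fps = fps, units = units, mm_per_px = mm_per_px,
                 bodyparts = bodyparts, x = x, y = y,
                 likelihood = likelihood, mask = mask),
            class = "tracked_trajectory")
}

#' @export
print.tracked_trajectory <- function(x, ...) {
  cat(sprintf("<tracked_trajectory> %s view: %d frames, %d parts (%s), %s, %.6g fps; %d masked samples\n",
              x$view, nrow(x$x), length(x$bodyparts),
              paste(x$bodyparts, collapse = ", "), x$units, x$fps,
              sum(x$mask)))
  invisible(x)
}

n_frames <- function(traj) nrow(traj$x)

#' Frame times in seconds
#'
#' @param traj a [tracked_trajectory()].
#' @return Numeric vector; frame i (0-based) maps to i / fps seconds.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1) / traj$fps

#' Read a pose-tracking table in the DeepLabCut CSV dialect
#'
#' Parses the three-header-row export dialect (scorer / bodyparts / coords)
#' with per-part `x`, `y`, `likelihood` columns. Columns are located by the
#' bodyparts/coords header names, so column order does not matter.
#'
#' @param source path to a CSV file.
#' @param view camera view tag for the resulting trajectory.
#' @param fps frames per second recorded on the trajectory.
#' @return An uncalibrated [tracked_trajectory()].
#' @export
read_tracking_table <- function(source, view = c("front", "side", "ventral"),
                                fps = 294.1) {
  view <- match.arg(view)
  if (grepl("\\.(h5|hdf5)$", source, ignore.case = TRUE)) {
    stop_handkin("HDF5 tracking containers are not supported; export the CSV dialect instead",
                 "handkin_format_error")
  }
  lines <- readLines(source)
  if (length(lines) < 4L) {
    stop_handkin("tracking table needs 3 header rows and at least one frame",
                 "handkin_format_error")
  }
  hdr <- lapply(lines[1:3], function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  labels <- vapply(hdr, `[`, "", 1L)
  if (!identical(tolower(labels), c("scorer", "bodyparts", "coords"))) {
    stop_handkin("expected header rows labelled scorer / bodyparts / coords",
                 "handkin_format_error")
  }
  parts_row <- hdr[[2]][-1L]
  coords_row <- tolower(hdr[[3]][-1L])
  if (length(parts_row) != length(coords_row)) {
    stop_handkin("bodyparts and coords header rows differ in length",
                 "handkin_format_error")
  }
  bad <- !coords_row %in% c("x", "y", "likelihood")
  if (any(bad)) {
    stop_handkin(sprintf("unknown coords label '%s'", coords_row[bad][1L]),
                 "handkin_format_error")
  }
  parts <- unique(parts_row)
  for (p in parts) {
    have <- sort(coords_row[parts_row == p])
    if (!identical(have, c("likelihood", "x", "y"))) {
      stop_handkin(sprintf("body part '%s' is missing a coords column (found: %s)",
                           p, paste(coords_row[parts_row == p], collapse = ", ")),
                   "handkin_format_error")
    }
  }
  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  cells <- strsplit(data_lines, ",", fixed = TRUE)
  ncol_expected <- length(parts_row) + 1L
  nf <- length(cells)
  vals <- matrix(NA_real_, nf, length(parts_row))
  for (i in seq_len(nf)) {
    row <- cells[[i]]
    if (length(row) != ncol_expected) {
      stop_handkin(sprintf("row %d has %d fields, expected %d", i, length(row),
                           ncol_expected), "handkin_parse_error")
    }
    v <- suppressWarnings(as.numeric(row[-1L]))
    blank <- !nzchar(trimws(row[-1L]))
    if (any(is.na(v) & !blank)) {
      stop_handkin(sprintf("non-numeric cell in data row %d", i),
                   "handkin_parse_error")
    }
    vals[i, ] <- v
  }
  pick <- function(part, coord) vals[, which(parts_row == part & coords_row == coord), drop = TRUE]
  x <- vapply(parts, pick, numeric(nf), coord = "x")
  y <- vapply(parts, pick, numeric(nf), coord = "y")
  lik <- vapply(parts, pick, numeric(nf), coord = "likelihood")
  if (nf == 1L) { # vapply drops to vector
    x <- matrix(x, 1L); y <- matrix(y, 1L); lik <- matrix(lik, 1L)
  }
  tracked_trajectory(x, y, lik, bodyparts = parts, view = view, fps = fps)
}

#' Write a trajectory in the DeepLabCut CSV dialect
#'
#' Inverse of [read_tracking_table()]; full numeric precision is kept so a
#' write/read round-trip reproduces the trajectory exactly.
#'
#' @param traj a [tracked_trajectory()].
#' @param path output CSV path.
#' @param scorer scorer name placed in the first header row.
#' @return `path`, invisibly.
#' @export
write_tracking_table <- function(traj, path, scorer = "handkin") {
  parts <- traj$bodyparts
  hdr1 <- c("scorer", rep(scorer, 3L * length(parts)))
  hdr2 <- c("bodyparts", rep(parts, each = 3L))
  hdr3 <- c("coords", rep(c("x", "y", "likelihood"), length(parts)))
  nf <- n_frames(traj)
  cols <- vector("list", 3L * length(parts))
  for (j in seq_along(parts)) {
    cols[[3L * j - 2L]] <- traj$x[, j]
    cols[[3L * j - 1L]] <- traj$y[, j]
    cols[[3L * j]] <- traj$likelihood[, j]
  }
  body <- do.call(cbind, c(list(seq_len(nf) - 1L),
                           lapply(cols, format_full)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(hdr1, collapse = ","),
               paste(hdr2, collapse = ","),
               paste(hdr3, collapse = ","),
               apply(body, 1L, paste, collapse = ",")), con)
  invisible(path)
}

format_full <- function(v) {
  out <- vapply(v, function(z) {
    if (is.na(z)) "" else sprintf("%.17g", z)
  }, "")
  out
}

#' Mask low-quality tracking samples
#'
#' Marks samples below a likelihood floor and/or within explicit exclusion
#' intervals as invalid. Masked samples propagate as missing values through
#' all downstream features; the original values are retained under the mask.
#' Masking is idempotent and the two criteria commute.
#'
#' @param traj a [tracked_trajectory()].
#' @param likelihood_floor samples with likelihood strictly below this value
#'   are masked. Default 0 (no likelihood masking), mirroring a workflow in
#'   which poor tracking is excluded by explicit intervals rather than a
#'   confidence threshold.
#' @param exclusion_intervals optional two-column matrix or data.frame of
#'   half-open frame intervals `[start, end)`, 0-based, to mask for all parts.
#' @return The trajectory with an updated mask.
#' @export
mask_low_quality <- function(traj, likelihood_floor = 0,
                             exclusion_intervals = NULL) {
  assert_scalar_number(likelihood_floor, "likelihood_floor")
  if (likelihood_floor < 0 || likelihood_floor > 1) {
    stop_handkin("likelihood_floor must lie in [0, 1]", "handkin_parameter_error")
  }
  mask <- traj$mask
  if (likelihood_floor > 0) {
    mask <- mask | (!is.na(traj$likelihood) & traj$likelihood < likelihood_floor)
  }
  if (!is.null(exclusion_intervals)) {
    iv <- as.matrix(exclusion_intervals)[, 1:2, drop = FALSE]
    nf <- n_frames(traj)
    for (k in seq_len(nrow(iv))) {
      s <- iv[k, 1L]; e <- iv[k, 2L]
      if (s < 0 || e > nf || s >= e) {
        stop_handkin(sprintf("exclusion interval [%g, %g) outside [0, %d)", s, e, nf),
                     "handkin_parameter_error")
      }
      mask[(s + 1L):e, ] <- TRUE
    }
  }
  traj$mask <- mask
  traj
}

#' Calibrate a trajectory from pixels to millimetres
#'
#' Scales positions by the ruler-derived mm-per-pixel factor and records the
#' frame rate; the trajectory's unit state flips to mm. Calibrating twice is
#' an error so pixel and mm units can never be mixed.
#'
#' @param traj an uncalibrated [tracked_trajectory()].
#' @param mm_per_px positive scale factor (mm per pixel), or a `calibration`
#'   list with entries `mm_per_px` and `fps`.
#' @param fps optional frame rate override.
#' @return The calibrated trajectory (positions in mm).
#' @export
calibrate <- function(traj, mm_per_px, fps = NULL) {
  if (is.list(mm_per_px)) {
    fps <- fps %||% mm_per_px$fps
    mm_per_px <- mm_per_px$mm_per_px
  }
  assert_scalar_number(mm_per_px, "mm_per_px", positive = TRUE)
  if (!is.null(fps)) assert_scalar_number(fps, "fps", positive = TRUE)
  if (identical(traj$units, "mm")) {
    stop_handkin("trajectory is already calibrated to mm", "handkin_state_error")
  }
  traj$x <- traj$x * mm_per_px
  traj$y <- traj$y * mm_per_px
  traj$units <- "mm"
  traj$mm_per_px <- mm_per_px
  if (!is.null(fps)) traj$fps <- fps
  traj
}
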