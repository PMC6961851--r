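#' Autocorrelogram periodicity of regrip bursts
#'
#' Regrips cluster into rapid bursts. Groups of regrips with consecutive
#' inter-regrip intervals of at most 300 ms are identified; for each group
#' the D trace from 300 ms before the first regrip to 300 ms after the last
#' is mean-subtracted and autocorrelated to a maximum lag of 300 ms
#' (normalized by its zero-lag value). The across-group mean correlogram is
#' min-max normalized to [0, 1], and the burst periodicity is the reciprocal
#' of the lag of its largest local maximum to the right of the central peak
#' (beyond the first positive-lag local minimum).
#'
#' @param D numeric trace (mm) or `feature_series`.
#' @param events regrip event data.frame.
#' @param fps frames per second.
#' @param max_lag maximum correlogram lag in seconds (default 0.3).
#' @param max_interval maximum intra-group inter-regrip interval in seconds
#'   (default 0.3).
#' @return A list of class `correlogram`: `lag` (s, symmetric about 0),
#'   `values` (min 0, max 1), `periodicity_hz`, `n_groups`. When no
#'   qualifying group exists, `periodicity_hz` is `NA` and `n_groups` 0.
#' @export
regrip_autocorrelogram <- function(D, events, fps = NULL, max_lag = 0.3,
                                   max_interval = 0.3) {
  ser <- extract_series(D, "D", fps)
  x <- ser$x; fps <- ser$fps
  lag_frames <- round(max_lag * fps)
  times <- sort(events$peak_time)
  groups <- split_into_groups(times, max_interval)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L) {
    warning(warningCondition("no regrip group with intervals <= max_interval",
                             class = "handkin_undefined_result"))
    return(structure(list(lag = ((-lag_frames):lag_frames) / fps,
                          values = NULL, periodicity_hz = NA_real_,
                          n_groups = 0L), class = "correlogram"))
  }
  acfs <- matrix(NA_real_, length(groups), lag_frames + 1L)
  for (g in seq_along(groups)) {
    tg <- groups[[g]]
    i0 <- max(1L, round((min(tg) - max_lag) * fps) + 1L)
    i1 <- min(length(x), round((max(tg) + max_lag) * fps) + 1L)
    seg <- x[i0:i1]
    seg <- seg[!is.na(seg)]
    if (length(seg) < 3L) next
    seg <- seg - mean(seg)
    lmax <- min(lag_frames, length(seg) - 1L)
    ac <- stats::acf(seg, lag.max = lmax, type = "correlation",
                     demean = FALSE, plot = FALSE)$acf[, 1L, 1L]
    acfs[g, seq_along(ac)] <- ac
  }
  mean_ac <- colMeans(acfs, na.rm = TRUE)
  vals <- (mean_ac - min(mean_ac, na.rm = TRUE)) /
    (max(mean_ac, na.rm = TRUE) - min(mean_ac, na.rm = TRUE))
  # locate the first positive-lag local minimum (edge of the central peak),
  # then the largest local maximum beyond it
  periodicity <- NA_real_
  n <- length(vals)
  mins <- which(diff(sign(diff(vals))) > 0) + 1L
  if (length(mins)) {
    start <- mins[1L]
    maxs <- which(diff(sign(diff(vals))) < 0) + 1L
    maxs <- maxs[maxs > start]
    if (length(maxs)) {
      peak_lag <- maxs[which.max(vals[maxs])]
      periodicity <- fps / (peak_lag - 1L)
    }
  }
  structure(list(lag = ((-lag_frames):lag_frames) / fps,
                 values = c(rev(vals[-1L]), vals),
                 periodicity_hz = periodicity,
                 n_groups = length(groups)),
            class = "correlogram")
}

split_into_groups <- function(times, max_interval) {
  if (length(times) == 0L) return(list())
  brk <- c(0L, which(diff(times) > max_interval), length(times))
  lapply(seq_len(length(brk) - 1L),
         function(i) times[(brk[i] + 1L):brk[i + 1L]])
}

#' Bimanual asymmetry index of a regrip
#'
#' Computes the 2D path integral (sum of Euclidean step lengths) of each
#' hand's trajectory over the 40 ms window centered on the regrip peak, and
#' the signed index (right - left) / (right + left): 0 when both hands travel
#' the same distance, magnitude 1 when one hand is stationary; negative sign
#' means the left hand moved more, positive the right.
#'
#' @param left_hand,right_hand two-column (x, y) matrices or data.frames of
#'   hand positions (mm) per frame.
#' @param peak_time regrip peak time in seconds.
#' @param fps frames per second.
#' @param window window length in seconds centered on the peak (default
#'   0.04).
#' @return A list with `index`, `path_left`, `path_right`, `valid`.
#' @export
asymmetry_index <- function(left_hand, right_hand, peak_time, fps,
                            window = 0.04) {
  lh <- as.matrix(left_hand); rh <- as.matrix(right_hand)
  n <- nrow(lh)
  tt <- (seq_len(n) - 1L) / fps
  full_cover <- peak_time - window / 2 >= tt[1L] - 1e-12 &&
    peak_time + window / 2 <= tt[n] + 1e-12
  idx <- which(tt >= peak_time - window / 2 - 1e-12 &
                 tt <= peak_time + window / 2 + 1e-12)
  if (!full_cover || length(idx) < 2L || anyNA(lh[idx, ]) || anyNA(rh[idx, ])) {
    return(list(index = NA_real_, path_left = NA_real_,
                path_right = NA_real_, valid = FALSE))
  }
  path_len <- function(m) sum(sqrt(rowSums(diff(m[idx, , drop = FALSE])^2)))
  pl <- path_len(lh); pr <- path_len(rh)
  index <- if (pl + pr == 0) NA_real_ else (pr - pl) / (pr + pl)
  list(index = index, path_left = pl, path_right = pr, valid = TRUE)
}

#' Rolling coefficient of variation around regrips
#'
#' Computes the ratio of the standard deviation to the mean of the trace in
#' a 40 ms sliding window, then contrasts the median CV of windows centered
#' within 20 ms of a regrip peak against the median elsewhere. Windows with
#' non-positive mean yield a missing CV.
#'
#' @param series numeric trace (D in mm, or theta in degrees) or
#'   `feature_series` column source.
#' @param events regrip event data.frame.
#' @param fps frames per second.
#' @param window sliding-window length in seconds (default 0.04).
#' @param near within this time of a peak a window counts as regrip-adjacent
#'   (default 0.02 s).
#' @return A list with `cv` (per window center, NA where undefined),
#'   `median_cv_regrip`, `median_cv_elsewhere`.
#' @export
rolling_cv_contrast <- function(series, events, fps = NULL, window = 0.04,
                                near = 0.02) {
  ser <- extract_series(series, "D", fps)
  x <- ser$x; fps <- ser$fps
  w <- max(3L, round(window * fps))
  if (w %% 2L == 0L) w <- w + 1L
  kern <- rep(1 / w, w)
  m <- as.numeric(stats::filter(x, kern, sides = 2L))
  q <- as.numeric(stats::filter(x^2, kern, sides = 2L))
  v <- (q - m^2) * w / (w - 1)
  v[v < 0] <- 0
  cv <- sqrt(v) / m
  cv[is.na(m) | m <= 0] <- NA_real_
  tcent <- (seq_along(x) - 1L) / fps
  near_peak <- rep(FALSE, length(x))
  for (tp in events$peak_time) {
    near_peak <- near_peak | abs(tcent - tp) <= near + 1e-12
  }
  list(cv = cv,
       median_cv_regrip = stats::median(cv[near_peak], na.rm = TRUE),
       median_cv_elsewhere = stats::median(cv[!near_peak], na.rm = TRUE))
}

#' Grip-angle change around regrips
#'
#' For each regrip, the baseline is the median inter-D3 angle over the epoch
#' 60 to 20 ms before the peak; the reported values are the median absolute
#' deviation of the angle from this baseline during the baseline epoch and
#' during the post-regrip epoch 20 to 60 ms after the peak. The measure is
#' invariant to adding a constant angle.
#'
#' @param theta numeric angle trace (degrees) or `feature_series`.
#' @param events regrip event data.frame.
#' @param fps frames per second.
#' @return Data.frame per event: `baseline_dev`, `post_dev` (degrees),
#'   `valid`.
#' @export
theta_change <- function(theta, events, fps = NULL) {
  ser <- extract_series(theta, "theta", fps)
  x <- ser$x; fps <- ser$fps
  n <- length(x)
  out <- data.frame(baseline_dev = rep(NA_real_, nrow(events)),
                    post_dev = NA_real_, valid = FALSE)
  for (i in seq_len(nrow(events))) {
    p <- events$peak_frame[i] + 1L
    base_idx <- (p + round(-0.06 * fps)):(p + round(-0.02 * fps))
    post_idx <- (p + round(0.02 * fps)):(p + round(0.06 * fps))
    if (min(base_idx) < 1L || max(post_idx) > n) next
    baseline <- stats::median(x[base_idx], na.rm = TRUE)
    if (is.na(baseline)) next
    out$baseline_dev[i] <- stats::median(abs(x[base_idx] - baseline), na.rm = TRUE)
    out$post_dev[i] <- stats::median(abs(x[post_idx] - baseline), na.rm = TRUE)
    out$valid[i] <- TRUE
  }
  out
}
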