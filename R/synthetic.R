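#' Parameters for the synthetic food-handling session generator
#'
#' Defaults reproduce the statistical structure the analysis assumes:
#' alternating holding/oromanual phases with lognormal durations (medians
#' 0.30 s and 0.25 s), state-dependent posture levels (holding L 5.1 mm,
#' oromanual L 2.7 mm; holding D 5.3 mm, oromanual D 6.0 mm — the postural
#' modes separate mainly along L, with a modest widening of the bimanual
#' grip during handling), logistic transition ramps (50 ms 10-90% rise),
#' short bursts of Gaussian regrip pulses on D during oromanual phases
#' (burst size 1 + Poisson, intra-burst interval 65 +/- 5 ms, amplitude
#' 1.5 mm, sigma 7.2 ms, overall event rate on the order of 2 Hz) with a
#' per-pulse bimanual asymmetry draw, Gaussian sniff dips on the ventral L
#' during holding phases (depth 3 mm, sigma 34 ms, placed 120 ms before the
#' phase end), isotropic tracking noise and random dropouts. The ventral
#' view is an independent projection whose latent trace models the
#' holding-phase geometry that sniff analysis operates on: a holding-level
#' baseline carrying the sniff dips.
#'
#' @param fps frames per second (default 294.1).
#' @param duration session length in seconds.
#' @param holding_median,oromanual_median median phase durations (s).
#' @param duration_sdlog lognormal sdlog of phase durations.
#' @param L_holding,L_oromanual,D_holding,D_oromanual state means (mm).
#' @param ramp transition 10-90% rise time (s), logistic.
#' @param jitter_sd slow posture jitter sd (mm).
#' @param theta_sd slow inter-D3 angle wander sd (degrees).
#' @param burst_prob probability an oromanual phase contains a regrip burst.
#' @param burst_size_mean mean number of pulses beyond the first in a burst
#'   (Poisson).
#' @param burst_interval,burst_jitter_sd intra-burst interval mean and
#'   jitter sd (s).
#' @param pulse_amp,pulse_sigma regrip pulse amplitude (mm) and Gaussian
#'   sigma (s).
#' @param asym_range per-event asymmetry drawn uniformly on
#'   `[-asym_range, asym_range]`.
#' @param sniff_prob probability an eligible holding phase contains a sniff.
#' @param sniff_offset sniff peak placement before the holding-phase end (s).
#' @param dip_depth,dip_sigma sniff dip depth (mm) and Gaussian sigma (s).
#' @param noise_sd isotropic tracking noise sd (mm).
#' @param dropout_rate per-sample probability of a tracking dropout.
#' @param mm_per_px spatial calibration used to express the emitted
#'   trajectories in pixels.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(fps = 294.1, duration = 60,
                             holding_median = 0.30, oromanual_median = 0.25,
                             duration_sdlog = 0.3,
                             L_holding = 5.1, L_oromanual = 2.7,
                             D_holding = 5.3, D_oromanual = 6.0,
                             ramp = 0.05, jitter_sd = 0.08, theta_sd = 3,
                             burst_prob = 0.75, burst_size_mean = 0.7,
                             burst_interval = 0.065,
                             burst_jitter_sd = 0.005,
                             pulse_amp = 1.5, pulse_sigma = 0.0072,
                             asym_range = 0.8,
                             sniff_prob = 0.3, sniff_offset = 0.12,
                             dip_depth = 3, dip_sigma = 0.034,
                             noise_sd = 0.02, dropout_rate = 0.001,
                             mm_per_px = 0.05) {
  p <- as.list(environment())
  for (nm in c("fps", "duration", "holding_median", "oromanual_median",
               "pulse_amp", "pulse_sigma", "dip_depth", "dip_sigma",
               "burst_interval", "mm_per_px")) {
    assert_scalar_number(p[[nm]], nm, positive = TRUE)
  }
  stopifnot(p$L_holding >= 0, p$L_holding <= 20, p$L_oromanual >= 0,
            p$L_oromanual <= 20, p$D_holding <= 20, p$D_oromanual <= 20)
  structure(p, class = "generator_params")
}

# smoothed gaussian noise with the requested marginal sd
smooth_noise <- function(n, sd, width) {
  if (sd <= 0) return(numeric(n))
  z <- stats::rnorm(n)
  k <- max(3L, as.integer(width))
  m <- as.numeric(stats::filter(z, rep(1 / k, k), circular = TRUE))
  s <- stats::sd(m)
  if (is.na(s) || s == 0) return(numeric(n))
  m * sd / s
}

# logistic step train: level_1 + sum of step changes blended at boundaries
logistic_levels <- function(t, boundary_times, levels, ramp) {
  scale <- ramp / (2 * log(9)) # 10-90% rise = 2*ln(9)*scale
  out <- rep(levels[1L], length(t))
  for (k in seq_along(boundary_times)) {
    step <- levels[k + 1L] - levels[k]
    out <- out + step / (1 + exp(-(t - boundary_times[k]) / scale))
  }
  out
}

# add Gaussian pulses (possibly signed) to a trace; returns the summed
# contribution of `weights[i] * amp * exp(-(t - times[i])^2 / (2 sigma^2))`
gaussian_pulses <- function(t, times, amp, sigma, weights = rep(1, length(times))) {
  out <- numeric(length(t))
  if (length(times) == 0L) return(out)
  dt <- t[2L] - t[1L]
  half <- ceiling(5 * sigma / dt)
  for (i in seq_along(times)) {
    c0 <- round(times[i] / dt) + 1L
    idx <- max(1L, c0 - half):min(length(t), c0 + half)
    out[idx] <- out[idx] +
      weights[i] * amp * exp(-(t[idx] - times[i])^2 / (2 * sigma^2))
  }
  out
}

#' Generate a synthetic food-handling session with ground truth
#'
#' Simulates one session: alternating phase durations are drawn, latent
#' L(t)/D(t) traces built from state means with logistic ramps and slow
#' jitter, regrip pulses superimposed on D during oromanual phases (each
#' pulse's motion split between the hands by its asymmetry draw), sniff dips
#' superimposed on the ventral L during holding phases, and the latent
#' series embedded into 2D image coordinates so that recomputing L, D and
#' theta from the emitted (noiseless) coordinates recovers the latent series
#' exactly. Tracking noise and dropouts are then added and the session
#' emitted as uncalibrated pixel trajectories in the front and ventral
#' views. Identical seeds give identical output.
#'
#' @param params a [generator_params()].
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return A list with `front` and `ventral` [tracked_trajectory()] objects
#'   (pixels, uncalibrated) and `truth`: the true [ethogram()], regrip times
#'   and asymmetries, sniff times, the latent `L`/`D`/`theta`/`L_ventral`
#'   series, the calibration, and a parameter echo.
#' @export
generate_session <- function(params = generator_params(), seed) {
  if (missing(seed)) {
    stop_handkin("a seed is mandatory for reproducibility", "handkin_parameter_error")
  }
  set.seed(seed)
  fps <- params$fps
  n <- round(params$duration * fps)
  if (params$duration < 0.2 || n < 10L) {
    stop_handkin("duration too short to fit one phase", "handkin_parameter_error")
  }
  t <- (seq_len(n) - 1L) / fps

  # 1) alternating phase durations (holding first), truncated at session end
  phases <- character(0); durs <- numeric(0)
  cum <- 0; ph <- "holding"
  while (cum < params$duration) {
    med <- if (ph == "holding") params$holding_median else params$oromanual_median
    d <- max(0.06, stats::rlnorm(1L, meanlog = log(med), sdlog = params$duration_sdlog))
    phases <- c(phases, ph); durs <- c(durs, d)
    cum <- cum + d
    ph <- if (ph == "holding") "oromanual" else "holding"
  }
  starts_s <- cumsum(c(0, durs[-length(durs)]))
  start_frames <- round(starts_s * fps)
  eth <- ethogram(start_frames, phases, n)
  seg_start_s <- eth$start / fps
  seg_end_s <- eth$end / fps

  # 2) latent posture levels with logistic ramps + slow jitter
  lv_L <- ifelse(phases == "holding", params$L_holding, params$L_oromanual)
  lv_D <- ifelse(phases == "holding", params$D_holding, params$D_oromanual)
  bts <- starts_s[-1L]
  L_base <- logistic_levels(t, bts, lv_L, params$ramp) +
    smooth_noise(n, params$jitter_sd, round(0.3 * fps))
  D_base <- logistic_levels(t, bts, lv_D, params$ramp) +
    smooth_noise(n, params$jitter_sd, round(0.3 * fps))
  theta_l <- smooth_noise(n, params$theta_sd, round(0.5 * fps)) # degrees

  # 3) short regrip bursts on D during oromanual phases
  regrip_times <- numeric(0); regrip_asym <- numeric(0)
  for (i in which(eth$phase == "oromanual")) {
    span <- c(seg_start_s[i] + 0.04, seg_end_s[i] - 0.04)
    if (diff(span) < 0.02 || stats::runif(1L) > params$burst_prob) next
    n_pulses <- 1L + stats::rpois(1L, params$burst_size_mean)
    tp <- span[1L] + stats::runif(1L, 0, 0.02)
    for (k in seq_len(n_pulses)) {
      if (tp > span[2L]) break
      regrip_times <- c(regrip_times, tp)
      regrip_asym <- c(regrip_asym,
                       stats::runif(1L, -params$asym_range, params$asym_range))
      tp <- tp + params$burst_interval + stats::rnorm(1L, 0, params$burst_jitter_sd)
    }
  }
  w_right <- (1 + regrip_asym) / 2
  w_left <- (1 - regrip_asym) / 2
  disp_R <- gaussian_pulses(t, regrip_times, params$pulse_amp,
                            params$pulse_sigma, w_right)
  disp_L <- gaussian_pulses(t, regrip_times, params$pulse_amp,
                            params$pulse_sigma, w_left)

  # 4) sniff dips on the ventral L during holding phases; the ventral
  # latent is a holding-level baseline (the geometry sniff analysis uses),
  # not a re-projection of the front view
  sniff_times <- numeric(0)
  Lv_base <- params$L_holding + smooth_noise(n, params$jitter_sd,
                                             round(0.3 * fps))
  for (i in which(eth$phase == "holding")) {
    if (seg_end_s[i] - seg_start_s[i] < 0.3) next
    if (stats::runif(1L) > params$sniff_prob) next
    tp <- seg_end_s[i] - params$sniff_offset
    # sniffs are sparse (~0.2 Hz); successive dips never crowd within the
    # detector's 250 ms separation criterion
    if (length(sniff_times) && tp - sniff_times[length(sniff_times)] < 0.3) next
    sniff_times <- c(sniff_times, tp)
  }
  Lv <- pmax(0.3, Lv_base - gaussian_pulses(t, sniff_times, params$dip_depth,
                                            params$dip_sigma))

  # 5) embed into image coordinates (y down); theta is realized exactly
  th <- theta_l * pi / 180
  ux <- cos(th); uy <- -sin(th)
  nose <- c(12.8, 5.0)
  davg0_x <- rep(nose[1L], n); davg0_y <- nose[2L] + L_base
  ld3_x <- davg0_x - (D_base / 2 + disp_L) * ux
  ld3_y <- davg0_y - (D_base / 2 + disp_L) * uy
  rd3_x <- davg0_x + (D_base / 2 + disp_R) * ux
  rd3_y <- davg0_y + (D_base / 2 + disp_R) * uy
  # latent features from the noiseless geometry (exact round-trip)
  D_lat <- D_base + disp_L + disp_R
  Dax <- (ld3_x + rd3_x) / 2; Day <- (ld3_y + rd3_y) / 2
  L_lat <- sqrt((nose[1L] - Dax)^2 + (nose[2L] - Day)^2)

  nose_v <- c(12.8, 4.0)
  ldv_x <- nose_v[1L] - D_base / 2; rdv_x <- nose_v[1L] + D_base / 2
  ldv_y <- rdv_y <- nose_v[2L] + Lv

  mk_traj <- function(xs, ys, view) {
    parts <- c("nose", "LD3", "RD3")
    x <- do.call(cbind, xs); y <- do.call(cbind, ys)
    if (params$noise_sd > 0) {
      x <- x + stats::rnorm(length(x), 0, params$noise_sd)
      y <- y + stats::rnorm(length(y), 0, params$noise_sd)
    }
    lik <- matrix(stats::runif(n * 3L, 0.95, 1), n, 3L)
    mask <- matrix(FALSE, n, 3L)
    if (params$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * 3L) < params$dropout_rate, n, 3L)
      lik[drop] <- stats::runif(sum(drop), 0, 0.4)
      mask[drop] <- TRUE
    }
    tracked_trajectory(x / params$mm_per_px, y / params$mm_per_px, lik,
                       bodyparts = parts, view = view, fps = fps,
                       units = "px", mask = mask)
  }
  front <- mk_traj(list(rep(nose[1L], n), ld3_x, rd3_x),
                   list(rep(nose[2L], n), ld3_y, rd3_y), "front")
  ventral <- mk_traj(list(rep(nose_v[1L], n), ldv_x, rdv_x),
                     list(rep(nose_v[2L], n), ldv_y, rdv_y), "ventral")

  truth <- list(ethogram = eth,
                regrip_times = regrip_times, regrip_asym = regrip_asym,
                sniff_times = sniff_times,
                latent = data.frame(t = t, L = L_lat, D = D_lat,
                                    theta = theta_l, L_ventral = Lv),
                calibration = list(mm_per_px = params$mm_per_px, fps = fps),
                params = unclass(params), seed = seed)
  list(front = front, ventral = ventral, truth = truth)
}

#' Generate a tracked eye sweeping a circular arc
#'
#' Emulates the side-view input of head-angle estimation: the eye is placed
#' on a circle of the given center and radius at the programmed head angles
#' (image coordinates, y down), with optional isotropic tracking noise.
#'
#' @param center length-2 numeric (cx, cy), image units.
#' @param radius positive radius, image units.
#' @param angle_program numeric vector of true head angles (degrees,
#'   y-up convention).
#' @param noise_sd isotropic position noise sd.
#' @param seed RNG seed.
#' @param fps frames per second.
#' @return A list with `eye` (a [tracked_trajectory()], side view, part
#'   `"eye"`) and `true_angles` (degrees).
#' @export
generate_eye_arc <- function(center, radius, angle_program, noise_sd = 0,
                             seed = 1, fps = 294.1) {
  if (!is.numeric(radius) || radius <= 0) {
    stop_handkin("radius must be positive", "handkin_parameter_error")
  }
  set.seed(seed)
  th <- angle_program * pi / 180
  x <- center[1L] + radius * cos(th)
  y <- center[2L] - radius * sin(th) # image y down
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(x), 0, noise_sd)
    y <- y + stats::rnorm(length(y), 0, noise_sd)
  }
  eye <- tracked_trajectory(matrix(x, ncol = 1L), matrix(y, ncol = 1L),
                            matrix(1, length(x), 1L), bodyparts = "eye",
                            view = "side", fps = fps, units = "px")
  list(eye = eye, true_angles = angle_program)
}

#' Write a synthetic session to disk in the pipeline's input dialects
#'
#' Emits the tracking tables in the DeepLabCut CSV dialect, the ethogram in
#' the annotation CSV dialect, and the ground truth and parameters as JSON;
#' all files are re-readable by the package's readers with exact value
#' recovery.
#'
#' @param session result of [generate_session()].
#' @param directory output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(session, directory) {
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  paths <- c(front = file.path(directory, "front.csv"),
             ventral = file.path(directory, "ventral.csv"),
             ethogram = file.path(directory, "ethogram.csv"),
             truth = file.path(directory, "truth.json"),
             params = file.path(directory, "params.json"))
  write_tracking_table(session$front, paths[["front"]])
  write_tracking_table(session$ventral, paths[["ventral"]])
  write_ethogram(session$truth$ethogram, paths[["ethogram"]])
  truth <- session$truth
  truth$ethogram <- as.data.frame(truth$ethogram)
  truth$video_length_frames <- nrow(session$front$x)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  jsonlite::write_json(truth$params, paths[["params"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
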