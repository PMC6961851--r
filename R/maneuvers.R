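#' Detection parameters for regrip and sniff maneuvers
#'
#' Defaults reproduce the published detector settings: regrips are peaks in
#' the inter-hand distance D with topographic prominence >= 0.75 mm whose
#' flank slopes exceed 88 mm/s; sniffs are dips in the ventral snout-to-hands
#' distance reaching 2.5 mm or less, with prominence >= 1 mm (2.5 mm in
#' head-fixed recordings, which additionally cap the half-prominence width at
#' 600 ms) and pairwise separation >= 250 ms. Peak amplitude is referenced to
#' the mean of the pre (-300..-100 ms) and post (+100..+300 ms) baseline
#' windows, and FWHM is measured halfway between baseline and peak.
#'
#' @param regrip_min_prominence mm.
#' @param regrip_min_slope mm/s.
#' @param regrip_slope_rule `"both"` flanks must exceed the slope threshold
#'   (default; regrips are spike-like in both directions) or `"either"`.
#' @param sniff_max_dip_value mm; dips must reach at or below this value.
#' @param sniff_min_prominence mm (freely moving).
#' @param sniff_min_separation s.
#' @param sniff_head_fixed_min_prominence mm.
#' @param sniff_head_fixed_max_width s (width at half-prominence).
#' @param baseline_pre,baseline_post two-element numeric, seconds relative to
#'   the peak.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(regrip_min_prominence = 0.75,
                             regrip_min_slope = 88,
                             regrip_slope_rule = c("both", "either"),
                             sniff_max_dip_value = 2.5,
                             sniff_min_prominence = 1,
                             sniff_min_separation = 0.25,
                             sniff_head_fixed_min_prominence = 2.5,
                             sniff_head_fixed_max_width = 0.6,
                             baseline_pre = c(-0.3, -0.1),
                             baseline_post = c(0.1, 0.3)) {
  structure(list(regrip_min_prominence = regrip_min_prominence,
                 regrip_min_slope = regrip_min_slope,
                 regrip_slope_rule = match.arg(regrip_slope_rule),
                 sniff_max_dip_value = sniff_max_dip_value,
                 sniff_min_prominence = sniff_min_prominence,
                 sniff_min_separation = sniff_min_separation,
                 sniff_head_fixed_min_prominence = sniff_head_fixed_min_prominence,
                 sniff_head_fixed_max_width = sniff_head_fixed_max_width,
                 baseline_pre = baseline_pre, baseline_post = baseline_post),
            class = "detection_params")
}

new_events <- function(kind, index, fps, value, prominence, left_base, right_base) {
  data.frame(kind = rep(kind, length(index)),
             peak_frame = as.integer(index) - 1L,
             peak_time = (as.integer(index) - 1L) / fps,
             peak_value = value, prominence = prominence,
             left_base = as.integer(left_base) - 1L,
             right_base = as.integer(right_base) - 1L,
             stringsAsFactors = FALSE)
}

#' Detect regrip maneuvers in the inter-hand distance trace
#'
#' Regrips — rapid bimanual grip readjustments while the item is bite-held —
#' appear as sharp transient spikes in D. Candidates are local maxima with
#' topographic prominence at or above the threshold; each flank (between the
#' peak and its prominence base) must contain a single-frame slope exceeding
#' the slope threshold.
#'
#' @param D numeric vector, calibrated inter-D3 distance in mm (`NA` =
#'   masked), or a `feature_series`.
#' @param fps frames per second (taken from a `feature_series` if omitted).
#' @param params a [detection_params()].
#' @param eth optional [ethogram()]; when supplied, only events whose peak
#'   falls in an oromanual phase are kept.
#' @return Event data.frame: `kind`, `peak_frame` (0-based), `peak_time` (s),
#'   `peak_value`, `prominence`, `left_base`, `right_base`.
#' @export
detect_regrips <- function(D, fps = NULL, params = detection_params(),
                           eth = NULL) {
  ser <- extract_series(D, "D", fps)
  pk <- find_peaks(ser$x, min_prominence = params$regrip_min_prominence)
  if (nrow(pk)) {
    sl <- t(mapply(function(p, lb, rb) flank_slopes(ser$x, ser$fps, p, lb, rb),
                   pk$index, pk$left_base, pk$right_base))
    keep <- if (params$regrip_slope_rule == "both") {
      sl[, 1L] > params$regrip_min_slope & sl[, 2L] > params$regrip_min_slope
    } else {
      sl[, 1L] > params$regrip_min_slope | sl[, 2L] > params$regrip_min_slope
    }
    pk <- pk[keep, , drop = FALSE]
  }
  ev <- new_events("regrip", pk$index, ser$fps, pk$value, pk$prominence,
                   pk$left_base, pk$right_base)
  if (!is.null(eth) && nrow(ev)) {
    ph <- phase_per_frame(eth)
    inph <- ev$peak_frame + 1L <= length(ph) &
      !is.na(ph[pmin(ev$peak_frame + 1L, length(ph))]) &
      ph[pmin(ev$peak_frame + 1L, length(ph))] == "oromanual"
    ev <- ev[inph, , drop = FALSE]
  }
  ev[order(ev$peak_time), , drop = FALSE]
}

#' Detect sniff maneuvers in the ventral snout-to-hands distance
#'
#' Sniffs — brief movements bringing the held item under the nares — appear
#' as sharp dips in the ventral L trace. Detection operates on the additive
#' inverse of the trace: maxima of -L_ventral must reach a raw value of
#' -2.5 mm or higher (i.e. the item comes within 2.5 mm of the snout), exceed
#' the mode's prominence threshold, and be separated by at least 250 ms
#' (conflicts keep the more prominent peak, then the earlier on ties).
#' Head-fixed mode raises the prominence threshold and caps the peak width at
#' half-prominence.
#'
#' @param L_ventral numeric vector (mm) or `feature_series`.
#' @param fps frames per second.
#' @param params a [detection_params()].
#' @param mode `"freely_moving"` or `"head_fixed"`.
#' @return Event data.frame as in [detect_regrips()] (`peak_value` is the
#'   L_ventral value at the dip minimum).
#' @export
detect_sniffs <- function(L_ventral, fps = NULL, params = detection_params(),
                          mode = c("freely_moving", "head_fixed")) {
  mode <- match.arg(mode)
  ser <- extract_series(L_ventral, "L_ventral", fps)
  neg <- -ser$x
  prom_thresh <- if (mode == "head_fixed") {
    params$sniff_head_fixed_min_prominence
  } else {
    params$sniff_min_prominence
  }
  pk <- find_peaks(neg, min_prominence = prom_thresh)
  pk <- pk[pk$value >= -params$sniff_max_dip_value, , drop = FALSE]
  if (mode == "head_fixed" && nrow(pk)) {
    w <- mapply(function(p, v, pr) {
      width_at_level(neg, ser$fps, p, v - pr / 2)
    }, pk$index, pk$value, pk$prominence)
    pk <- pk[!is.na(w) & w <= params$sniff_head_fixed_max_width, , drop = FALSE]
  }
  pk <- enforce_separation(pk, ser$fps, params$sniff_min_separation)
  ev <- new_events("sniff", pk$index, ser$fps, ser$x[pk$index], pk$prominence,
                   pk$left_base, pk$right_base)
  ev[order(ev$peak_time), , drop = FALSE]
}

# greedy pruning: visit peaks by decreasing prominence (earlier peak on
# ties); drop any unvisited peak closer than min_sep to a kept one
enforce_separation <- function(pk, fps, min_sep) {
  if (nrow(pk) < 2L) return(pk)
  ord <- order(-pk$prominence, pk$index)
  keep <- logical(nrow(pk))
  dropped <- logical(nrow(pk))
  for (i in ord) {
    if (dropped[i]) next
    keep[i] <- TRUE
    close <- abs(pk$index - pk$index[i]) / fps < min_sep
    dropped[close & !keep] <- TRUE
  }
  pk[keep, , drop = FALSE]
}

extract_series <- function(x, col, fps) {
  if (inherits(x, "feature_series")) {
    fps <- fps %||% attr(x, "fps")
    nm <- if (col %in% names(x)) col else sub("_.*", "", col)
    return(list(x = x[[nm]], fps = fps))
  }
  if (is.null(fps)) {
    stop_handkin("fps must be supplied with a plain numeric series",
                 "handkin_parameter_error")
  }
  list(x = as.numeric(x), fps = fps)
}

#' Amplitude and FWHM of detected maneuvers
#'
#' For each event, the baseline is the mean of the samples in the pre
#' (-300..-100 ms) and post (+100..+300 ms) windows pooled; the amplitude is
#' the absolute difference between the trace value at the peak and this
#' baseline; the FWHM is the time between the linearly interpolated crossings
#' of the level halfway between baseline and peak adjacent to the peak. When
#' a half-level crossing is not found before the trace edge (or an NA gap),
#' the width is measured to the event's prominence base if available and the
#' event flagged `fwhm_truncated`. Events whose baseline windows fall outside
#' the trace are flagged invalid with missing metrics.
#'
#' @param series numeric trace (mm) or `feature_series` column source.
#' @param events event data.frame from a detector.
#' @param fps frames per second.
#' @param params a [detection_params()] (baseline window definition).
#' @return `events` with added columns `baseline_value`, `amplitude` (mm),
#'   `fwhm` (s), `valid`, `fwhm_truncated`.
#' @export
peak_metrics <- function(series, events, fps = NULL,
                         params = detection_params()) {
  col <- if (nrow(events) && events$kind[1L] == "sniff") "L_ventral" else "D"
  ser <- extract_series(series, col, fps)
  x <- ser$x; fps <- ser$fps
  n <- length(x)
  events$baseline_value <- NA_real_
  events$amplitude <- NA_real_
  events$fwhm <- NA_real_
  events$valid <- FALSE
  events$fwhm_truncated <- FALSE
  pre <- detection_params_windows(params)$pre
  post <- detection_params_windows(params)$post
  for (i in seq_len(nrow(events))) {
    p <- events$peak_frame[i] + 1L
    wpre <- p + round(pre * fps)
    wpost <- p + round(post * fps)
    if (wpre[1L] < 1L || wpost[2L] > n) next
    baseline <- mean(c(x[wpre[1L]:wpre[2L]], x[wpost[1L]:wpost[2L]]), na.rm = TRUE)
    if (is.nan(baseline) || is.na(x[p])) next
    events$baseline_value[i] <- baseline
    events$amplitude[i] <- abs(x[p] - baseline)
    events$valid[i] <- TRUE
    half <- (baseline + x[p]) / 2
    tl <- crossing_before(x, p, half)
    tr <- crossing_after(x, p, half)
    if (is.na(tl) && !is.na(events$left_base[i])) {
      tl <- events$left_base[i] + 1L
      events$fwhm_truncated[i] <- TRUE
    }
    if (is.na(tr) && !is.na(events$right_base[i])) {
      tr <- events$right_base[i] + 1L
      events$fwhm_truncated[i] <- TRUE
    }
    if (!is.na(tl) && !is.na(tr)) events$fwhm[i] <- (tr - tl) / fps
  }
  events
}

detection_params_windows <- function(params) {
  list(pre = params$baseline_pre, post = params$baseline_post)
}

#' Peak-aligned snippets and their average
#'
#' Samples the trace around every event on a common lag axis and averages
#' across events, ignoring out-of-range lags.
#'
#' @param series numeric trace or `feature_series` column source.
#' @param events event data.frame.
#' @param fps frames per second.
#' @param half_window seconds on either side of the peak.
#' @return List with `lag` (s), `snippets` (events x lags matrix) and `mean`.
#' @export
align_and_average <- function(series, events, fps = NULL, half_window = 0.1) {
  col <- if (nrow(events) && events$kind[1L] == "sniff") "L_ventral" else "D"
  ser <- extract_series(series, col, fps)
  x <- ser$x; fps <- ser$fps
  hw <- round(half_window * fps)
  lags <- (-hw):hw
  snip <- matrix(NA_real_, nrow(events), length(lags))
  for (i in seq_len(nrow(events))) {
    idx <- events$peak_frame[i] + 1L + lags
    ok <- idx >= 1L & idx <= length(x)
    snip[i, ok] <- x[idx[ok]]
  }
  list(lag = lags / fps, snippets = snip,
       mean = if (nrow(events)) colMeans(snip, na.rm = TRUE) else rep(NA_real_, length(lags)))
}

#' Maneuver rates and timing relative to phase transitions
#'
#' Computes the overall event rate and, for each event occurring in a holding
#' phase, the latency to the next oromanual onset and the time since the
#' previous oromanual offset. Events in the non-interior first/last segments
#' get missing latencies on the side where the neighboring phase is unknown;
#' events outside holding phases get missing latencies.
#'
#' @param events event data.frame.
#' @param eth an [ethogram()].
#' @param fps frames per second used to express the ethogram in seconds.
#' @param total_time analyzed time in seconds (denominator of the rate).
#' @return List with `rate` (Hz) and per-event `latency_next` /
#'   `latency_prev` (s).
#' @export
maneuver_rates_and_timing <- function(events, eth, fps, total_time) {
  assert_scalar_number(total_time, "total_time", positive = TRUE)
  n <- nrow(events)
  latency_next <- rep(NA_real_, n)
  latency_prev <- rep(NA_real_, n)
  oro <- eth[eth$phase == "oromanual", , drop = FALSE]
  for (i in seq_len(n)) {
    tp <- events$peak_time[i]
    f <- events$peak_frame[i]
    seg <- which(eth$start <= f & f < eth$end)
    if (length(seg) != 1L || eth$phase[seg] != "holding") next
    nxt <- oro$start[oro$start > f]
    prv <- oro$end[oro$end <= f]
    # a holding segment at the video edge has no known neighboring phase
    if (length(nxt) && seg < nrow(eth)) latency_next[i] <- min(nxt) / fps - tp
    if (length(prv) && seg > 1L) latency_prev[i] <- tp - max(prv) / fps
  }
  list(rate = n / total_time, latency_next = latency_next,
       latency_prev = latency_prev)
}

#' Export maneuver events as CSV with a JSON parameter sidecar
#'
#' @param events event data.frame (ideally after [peak_metrics()]).
#' @param path output CSV path; the detection parameters are written to
#'   `<path>.params.json` for provenance.
#' @param params the [detection_params()] used.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(events, path, params = detection_params()) {
  out <- events
  if ("fwhm" %in% names(out)) out$fwhm_ms <- out$fwhm * 1000
  utils::write.csv(out, path, row.names = FALSE)
  jsonlite::write_json(unclass(params), paste0(path, ".params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
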