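# Peak finding with topographic prominence.
#
# A local maximum's prominence is its height above the higher of the two
# minima separating it from higher terrain (or from the trace edge). These
# primitives underpin both maneuver detectors, so they are implemented here
# rather than borrowed: the detectors' contracts (flank slope between peak
# and prominence base, widths at half-prominence) need the base indices.

# indices of strict local maxima; plateaus report their midpoint.
# NA samples split the trace; maxima are found within contiguous runs.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  ok <- !is.na(x)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- integer(0)
  for (r in which(runs$values & runs$lengths >= 3L)) {
    s <- starts[r]; e <- ends[r]
    seg <- x[s:e]
    m <- length(seg)
    i <- 2L
    while (i <= m - 1L) {
      if (seg[i] > seg[i - 1L]) {
        j <- i
        while (j < m && seg[j + 1L] == seg[i]) j <- j + 1L
        if (j < m && seg[j + 1L] < seg[i]) {
          out <- c(out, s - 1L + (i + j) %/% 2L)
          i <- j + 1L
        } else {
          i <- j + 1L
        }
      } else {
        i <- i + 1L
      }
    }
  }
  sort(out)
}

# topographic prominence and base (flanking-minimum) indices of one peak,
# searched within the contiguous non-NA run [lo, hi] containing it.
peak_prominence <- function(x, p, lo = NULL, hi = NULL) {
  n <- length(x)
  if (is.null(lo)) { lo <- p; while (lo > 1L && !is.na(x[lo - 1L])) lo <- lo - 1L }
  if (is.null(hi)) { hi <- p; while (hi < n && !is.na(x[hi + 1L])) hi <- hi + 1L }
  v <- x[p]
  # left side
  lmin <- v; lbase <- p
  i <- p - 1L
  while (i >= lo) {
    if (x[i] > v) break
    if (x[i] < lmin) { lmin <- x[i]; lbase <- i }
    i <- i - 1L
  }
  rmin <- v; rbase <- p
  i <- p + 1L
  while (i <= hi) {
    if (x[i] > v) break
    if (x[i] < rmin) { rmin <- x[i]; rbase <- i }
    i <- i + 1L
  }
  list(prominence = v - max(lmin, rmin), left_base = lbase, right_base = rbase)
}

# all local maxima with prominence >= min_prominence
find_peaks <- function(x, min_prominence = 0) {
  idx <- local_maxima(x)
  if (length(idx) == 0L) {
    return(data.frame(index = integer(0), value = numeric(0),
                      prominence = numeric(0), left_base = integer(0),
                      right_base = integer(0)))
  }
  # run bounds computed once: per-peak edge walks are O(n) otherwise
  ok <- !is.na(x)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  run_of <- findInterval(idx, starts)
  pr <- lapply(seq_along(idx), function(k) {
    peak_prominence(x, idx[k], starts[run_of[k]], ends[run_of[k]])
  })
  out <- data.frame(index = idx, value = x[idx],
                    prominence = vapply(pr, `[[`, 0, "prominence"),
                    left_base = vapply(pr, function(z) as.integer(z$left_base), 0L),
                    right_base = vapply(pr, function(z) as.integer(z$right_base), 0L))
  out[out$prominence >= min_prominence, , drop = FALSE]
}

# maximum absolute single-step slope (units/s) on each flank between the
# peak and its prominence base
flank_slopes <- function(x, fps, peak, left_base, right_base) {
  rising <- if (left_base < peak) max(abs(diff(x[left_base:peak]))) * fps else 0
  falling <- if (right_base > peak) max(abs(diff(x[peak:right_base]))) * fps else 0
  c(rising = rising, falling = falling)
}

# width (s) at a given height level, by linear interpolation of the
# crossings adjacent to the peak; NA side if no crossing before the run edge
width_at_level <- function(x, fps, peak, level) {
  tl <- crossing_before(x, peak, level)
  tr <- crossing_after(x, peak, level)
  if (is.na(tl) || is.na(tr)) return(NA_real_)
  (tr - tl) / fps
}

# fractional index (1-based) where x crosses `level` walking left from peak
crossing_before <- function(x, peak, level) {
  sgn <- sign(x[peak] - level)
  i <- peak - 1L
  while (i >= 1L && !is.na(x[i])) {
    if (sign(x[i] - level) != sgn && x[i] != x[i + 1L]) {
      return(i + (level - x[i]) / (x[i + 1L] - x[i]))
    }
    i <- i - 1L
  }
  NA_real_
}

crossing_after <- function(x, peak, level) {
  sgn <- sign(x[peak] - level)
  n <- length(x)
  i <- peak + 1L
  while (i <= n && !is.na(x[i])) {
    if (sign(x[i] - level) != sgn && x[i] != x[i - 1L]) {
      return(i - 1L + (level - x[i - 1L]) / (x[i] - x[i - 1L]))
    }
    i <- i + 1L
  }
  NA_real_
}
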