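#' Phase alternation statistics from an ethogram
#'
#' Quantifies the oromanual/holding alternation:
#' \itemize{
#'   \item `switch_rate` — segment boundaries interior to the ethogrammed
#'     span divided by the total ethogrammed duration (Hz);
#'   \item `duty_cycle` — total oromanual time over total time in either
#'     phase, using all segments;
#'   \item `phase_durations` — per-phase duration lists (s) from interior
#'     segments only, since the first and last segments' true durations are
#'     unknown.
#' }
#'
#' @param eth an [ethogram()].
#' @param fps frames per second.
#' @return A list of class `phase_stats` with `switch_rate`, `duty_cycle`
#'   and `phase_durations` (named list `oromanual`/`holding`).
#' @export
phase_statistics <- function(eth, fps) {
  assert_scalar_number(fps, "fps", positive = TRUE)
  if (nrow(eth) == 0L) {
    stop_handkin("empty ethogram", "handkin_insufficient_data_error")
  }
  total_frames <- eth$end[nrow(eth)] - eth$start[1L]
  total_s <- total_frames / fps
  n_switches <- nrow(eth) - 1L
  dur_s <- (eth$end - eth$start) / fps
  oro_s <- sum(dur_s[eth$phase == "oromanual"])
  interior <- eth$interior
  structure(list(
    switch_rate = n_switches / total_s,
    duty_cycle = oro_s / total_s,
    phase_durations = list(
      oromanual = dur_s[interior & eth$phase == "oromanual"],
      holding = dur_s[interior & eth$phase == "holding"])),
    class = "phase_stats")
}

#' Select the number of clusters with the L-method
#'
#' Finds the knee of an SSE-versus-k evaluation curve by fitting, for each
#' candidate knee c, least-squares lines to the points 1..c and c..k_max; the
#' candidate minimizing the length-weighted sum of the two residual RMSEs is
#' selected. Ties (all-linear curves) break to the smaller c.
#'
#' @param sse_curve within-cluster sum of squares for k = 1..k_max
#'   (k_max >= 4).
#' @return Selected k (integer).
#' @export
select_k_lmethod <- function(sse_curve) {
  kmax <- length(sse_curve)
  if (kmax < 4L) {
    stop_handkin("the L-method needs an evaluation curve with k_max >= 4",
                 "handkin_parameter_error")
  }
  ks <- seq_len(kmax)
  cand <- 2:(kmax - 1L)
  err <- vapply(cand, function(cc) {
    left <- ks <= cc
    right <- ks >= cc
    r1 <- line_rmse(ks[left], sse_curve[left])
    r2 <- line_rmse(ks[right], sse_curve[right])
    nl <- sum(left); nr <- sum(right)
    (nl * r1 + nr * r2) / (nl + nr)
  }, 0)
  best <- min(err)
  tol <- 1e-9 * max(1, abs(best))
  cand[which(err <= best + tol)[1L]]
}

line_rmse <- function(x, y) {
  fit <- stats::lm.fit(cbind(1, x), y)
  sqrt(mean(fit$residuals^2))
}

#' Recover the postural modes by k-means clustering of (L, D)
#'
#' Runs k-means on the non-missing (L, D) pairs in unscaled millimetres for
#' k = 1..k_max, with the stated number of random restarts keeping the
#' lowest-SSE solution per k, then selects k by the L-method. When k = 2 the
#' cluster with the smaller L centroid (hands nearer the mouth) is labeled
#' oromanual and the other holding.
#'
#' @param features a `feature_series` or data.frame with columns `L`, `D`.
#' @param k_max maximum k evaluated (default 10).
#' @param replicates random restarts per k (default 10).
#' @param rng_seed seed controlling the k-means initializations.
#' @return A list of class `cluster_result`: `k_selected`, `assignments`
#'   (per non-missing sample, in input order with NA for missing),
#'   `centroids` (k x 2, columns L and D), `phase_labels`, `sse_curve`,
#'   `degenerate`, `rng_seed`.
#' @export
cluster_phases <- function(features, k_max = 10, replicates = 10, rng_seed = 1) {
  pts <- cbind(L = features$L, D = features$D)
  ok <- stats::complete.cases(pts)
  pts_ok <- pts[ok, , drop = FALSE]
  if (nrow(pts_ok) < k_max) {
    stop_handkin(sprintf("need at least k_max = %d non-missing (L, D) samples", k_max),
                 "handkin_insufficient_data_error")
  }
  n_distinct <- nrow(unique(pts_ok))
  set.seed(rng_seed)
  degenerate <- n_distinct == 1L
  k_eval <- min(k_max, n_distinct)
  fits <- vector("list", k_eval)
  sse <- numeric(k_max)
  for (k in seq_len(k_eval)) {
    # Quick-TRANSfer / convergence warnings on heavily duplicated mode data
    # are benign here: the replicate with the lowest SSE is kept regardless
    fits[[k]] <- withCallingHandlers(
      stats::kmeans(pts_ok, centers = k, nstart = replicates, iter.max = 100),
      warning = function(w) {
        if (grepl("Quick-TRANSfer|did not converge", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    sse[k] <- fits[[k]]$tot.withinss
  }
  if (k_eval < k_max) sse[(k_eval + 1L):k_max] <- sse[k_eval]
  k_selected <- if (degenerate) 1L else select_k_lmethod(sse)
  k_selected <- min(k_selected, k_eval)
  fit <- fits[[k_selected]]
  assignments <- rep(NA_integer_, nrow(pts))
  assignments[ok] <- fit$cluster
  centroids <- fit$centers
  colnames(centroids) <- c("L", "D")
  phase_labels <- rep(NA_character_, k_selected)
  if (k_selected == 2L) {
    oro <- which.min(centroids[, "L"])
    phase_labels[oro] <- "oromanual"
    phase_labels[-oro] <- "holding"
  }
  structure(list(k_selected = k_selected, assignments = assignments,
                 centroids = centroids, phase_labels = phase_labels,
                 sse_curve = sse, degenerate = degenerate,
                 rng_seed = rng_seed),
            class = "cluster_result")
}

#' Smoothed 2D densities of (L, D) points with 10%-of-max contours
#'
#' Gaussian-kernel density per group on a shared grid over the [0, 20] mm
#' support in each dimension, normalized to a maximum of 1; the cross-group
#' average map is the mean of the normalized per-group maps; contour
#' polylines are extracted at 10% of each map's maximum. Bandwidths follow a
#' normal-reference rule per dimension; the kernel is truncated at the
#' support boundary (no boundary-corrected transform), which leaves the 10%
#' contour essentially unchanged for data away from 0 mm.
#'
#' @param points_by_group list of data.frames/matrices with columns L and D
#'   (mm), one per group (e.g. per animal).
#' @param grid_n grid resolution per dimension (default 128).
#' @param support two-element numeric, the common support (default
#'   `c(0, 20)` mm).
#' @return A list with per-group maps (`maps`, each `list(x, y, z, contour)`,
#'   z max-normalized to 1), the cross-group `average` map with its contour,
#'   and the grid vectors.
#' @export
density_contours <- function(points_by_group, grid_n = 128, support = c(0, 20)) {
  if (!is.list(points_by_group) || is.data.frame(points_by_group)) {
    points_by_group <- list(points_by_group)
  }
  maps <- lapply(points_by_group, function(p) {
    p <- as.matrix(as.data.frame(p)[, 1:2])
    p <- p[stats::complete.cases(p), , drop = FALSE]
    if (nrow(p) < 2L) {
      stop_handkin("need at least 2 points per group", "handkin_insufficient_data_error")
    }
    if (any(p < support[1L] | p > support[2L])) {
      warning("points outside the density support; their contribution is clipped")
    }
    h <- c(bw_normal_ref(p[, 1L]), bw_normal_ref(p[, 2L]))
    kd <- MASS::kde2d(p[, 1L], p[, 2L], h = h, n = grid_n, lims = rep(support, 2L))
    kd$z <- kd$z / max(kd$z)
    kd$contour <- grDevices::contourLines(kd$x, kd$y, kd$z, levels = 0.1)
    kd
  })
  avg_z <- Reduce(`+`, lapply(maps, `[[`, "z")) / length(maps)
  avg <- list(x = maps[[1L]]$x, y = maps[[1L]]$y, z = avg_z,
              contour = grDevices::contourLines(maps[[1L]]$x, maps[[1L]]$y,
                                                avg_z, levels = 0.1 * max(avg_z)))
  list(maps = maps, average = avg, grid_x = maps[[1L]]$x, grid_y = maps[[1L]]$y)
}

# Scott-type normal-reference bandwidth; MASS::kde2d uses h/4 as kernel sd
bw_normal_ref <- function(x) {
  h <- MASS::bandwidth.nrd(x)
  if (h <= 0) h <- 4 * 0.1 # degenerate spread: fall back to 0.1 mm kernel sd
  h
}

#' Rise time of a holding-to-oromanual phase transition
#'
#' Measures how fast L moves off its holding-phase baseline at a transition:
#' the baseline is the mean of L over 750 to 250 ms before the transition; a
#' line is fit through the last pre-transition crossings of 10% and 90% of
#' the difference between baseline and the transition value; the rise time
#' is the interval from where that line attains the baseline back to the
#' transition.
#'
#' @param L numeric trace (mm) or `feature_series`.
#' @param fps frames per second.
#' @param transition_time transition time in seconds (frame i is at i/fps).
#' @return Rise duration in seconds, or `NA` (with a warning condition class
#'   `handkin_undefined_result`) when the geometry is undefined (zero
#'   difference, or no crossings in the window).
#' @export
transition_rise_time <- function(L, fps = NULL, transition_time) {
  ser <- extract_series(L, "L", fps)
  x <- ser$x; fps <- ser$fps
  tt <- transition_time
  n <- length(x)
  ft <- (seq_len(n) - 1L) / fps
  if (tt - 0.75 < ft[1L] - 1e-12 || tt > ft[n] + 1e-12) {
    stop_handkin("trace must cover [transition - 0.75 s, transition]",
                 "handkin_parameter_error")
  }
  base_idx <- which(ft >= tt - 0.75 & ft <= tt - 0.25)
  baseline <- mean(x[base_idx], na.rm = TRUE)
  p <- which.min(abs(ft - tt))
  delta <- x[p] - baseline
  if (is.na(delta) || delta == 0) return(undefined_result("zero baseline-to-transition difference"))
  lvl10 <- baseline + 0.1 * delta
  lvl90 <- baseline + 0.9 * delta
  c10 <- last_crossing_before(x, p, lvl10)
  c90 <- last_crossing_before(x, p, lvl90)
  if (is.na(c10) || is.na(c90) || c10 == c90) {
    return(undefined_result("no 10%/90% crossings before the transition"))
  }
  t10 <- (c10 - 1) / fps; t90 <- (c90 - 1) / fps
  slope <- (lvl90 - lvl10) / (t90 - t10)
  t_base <- t10 + (baseline - lvl10) / slope
  max(0, tt - t_base)
}

# fractional 1-based index of the last crossing of `level` at or before p
last_crossing_before <- function(x, p, level) {
  i <- p
  while (i >= 2L && !is.na(x[i]) && !is.na(x[i - 1L])) {
    s1 <- x[i - 1L] - level
    s2 <- x[i] - level
    if (s1 == 0 && s2 == 0) { i <- i - 1L; next }
    if (s1 == 0) return(i - 1)
    if (s2 == 0) return(i)
    if (sign(s1) != sign(s2)) {
      return(i - 1L + (level - x[i - 1L]) / (x[i] - x[i - 1L]))
    }
    i <- i - 1L
  }
  NA_real_
}

undefined_result <- function(msg) {
  warning(warningCondition(msg, class = "handkin_undefined_result"))
  NA_real_
}
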