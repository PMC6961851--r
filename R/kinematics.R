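#' Derived kinematic features: L, D and the inter-D3 angle
#'
#' Computes, per frame, the two features that span the food-handling posture
#' space plus the inter-hand angle:
#' \itemize{
#'   \item `D` — Euclidean distance between the right and left D3 knuckles
#'     (hand separation, mm);
#'   \item `L` — Euclidean distance from the snout tip to `D_avg`, the
#'     midpoint of the two D3s (hand-to-mouth distance, mm);
#'   \item `theta` — orientation of the left-to-right D3 vector relative to
#'     the image horizontal, measured y-up, degrees in (-180, 180]. Only
#'     changes in theta are analyzed downstream, so the reference-axis
#'     convention is immaterial to results.
#' }
#' Any frame with a masked constituent sample yields missing features.
#' For side/ventral views the same snout-to-hands distance is reported under
#' `L_side`/`L_ventral`.
#'
#' @param traj a calibrated [tracked_trajectory()] containing the snout and
#'   both D3 parts.
#' @param nose,left_d3,right_d3 body-part names.
#' @return A `feature_series` data.frame with columns `frame`, `t`, `L`, `D`,
#'   `theta`, `Davg_x`, `Davg_y` (plus `L_side`/`L_ventral` aliases for those
#'   views), carrying `fps` as an attribute.
#' @export
compute_features <- function(traj, nose = "nose", left_d3 = "LD3",
                             right_d3 = "RD3") {
  if (!identical(traj$units, "mm")) {
    stop_handkin("trajectory must be calibrated to mm before computing features",
                 "handkin_state_error")
  }
  for (p in c(nose, left_d3, right_d3)) {
    if (!p %in% traj$bodyparts) {
      stop_handkin(sprintf("required body part '%s' absent from trajectory", p),
                   "handkin_configuration_error")
    }
  }
  get <- function(p) {
    bad <- traj$mask[, p]
    list(x = ifelse(bad, NA_real_, traj$x[, p]),
         y = ifelse(bad, NA_real_, traj$y[, p]))
  }
  no <- get(nose); ld <- get(left_d3); rd <- get(right_d3)
  dx <- rd$x - ld$x
  dy <- rd$y - ld$y
  D <- sqrt(dx^2 + dy^2)
  Davg_x <- (rd$x + ld$x) / 2
  Davg_y <- (rd$y + ld$y) / 2
  L <- sqrt((no$x - Davg_x)^2 + (no$y - Davg_y)^2)
  # image y is down; flip so angles are in the conventional y-up frame
  theta <- wrap_half_open(atan2(-dy, dx) * 180 / pi)
  theta[!is.na(D) & D == 0] <- NA_real_
  out <- data.frame(frame = seq_along(D) - 1L, t = frame_times(traj),
                    L = L, D = D, theta = theta,
                    Davg_x = Davg_x, Davg_y = Davg_y)
  if (traj$view == "ventral") out$L_ventral <- out$L
  if (traj$view == "side") out$L_side <- out$L
  attr(out, "fps") <- traj$fps
  attr(out, "view") <- traj$view
  class(out) <- c("feature_series", "data.frame")
  out
}

#' Principal components of per-frame pairwise body-part distances
#'
#' Forms, for every frame, the vector of Euclidean distances between every
#' unordered pair of tracked body parts, and decomposes the centered distance
#' matrix by PCA. In handling data the leading components are typically
#' driven by digit-to-nose distances and contralateral digit separations,
#' i.e. they correspond roughly to L and D.
#'
#' @param traj a calibrated [tracked_trajectory()] with at least two parts.
#' @return A list with `loadings` (pairs x components), `explained_variance`
#'   (per component), `pair_names`, `scores` and `n_frames_used`.
#' @export
pairwise_distance_pca <- function(traj) {
  if (!identical(traj$units, "mm")) {
    stop_handkin("trajectory must be calibrated to mm", "handkin_state_error")
  }
  parts <- traj$bodyparts
  if (length(parts) < 2L) {
    stop_handkin("need at least two body parts", "handkin_parameter_error")
  }
  pairs <- utils::combn(parts, 2L)
  xm <- traj$x; ym <- traj$y
  xm[traj$mask] <- NA_real_; ym[traj$mask] <- NA_real_
  dmat <- sapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    sqrt((xm[, a] - xm[, b])^2 + (ym[, a] - ym[, b])^2)
  })
  if (is.null(dim(dmat))) dmat <- matrix(dmat, nrow = 1L)
  pair_names <- paste(pairs[1L, ], pairs[2L, ], sep = "-")
  colnames(dmat) <- pair_names
  ok <- stats::complete.cases(dmat)
  if (sum(ok) < 3L) {
    stop_handkin("fewer than 3 fully tracked frames", "handkin_insufficient_data_error")
  }
  pc <- stats::prcomp(dmat[ok, , drop = FALSE], center = TRUE, scale. = FALSE)
  list(loadings = pc$rotation, explained_variance = pc$sdev^2,
       pair_names = pair_names, scores = pc$x, n_frames_used = sum(ok))
}

#' Export a feature series as tidy CSV
#'
#' @param features a `feature_series` from [compute_features()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
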