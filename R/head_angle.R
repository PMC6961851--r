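#' Pratt's algebraic circle fit
#'
#' Fits a circle to 2D points by minimizing the algebraic distance
#' `a*(x^2 + y^2) + b*x + c*y + d` under Pratt's normalization constraint
#' `b^2 + c^2 - 4*a*d = 1`, solved as a generalized eigenproblem of the
#' moment matrix. The fit is exact on noiseless circle samples and nearly
#' unbiased for small arcs. Data are centered before fitting for numerical
#' stability.
#'
#' @param points two-column (x, y) matrix or data.frame of at least 3
#'   non-collinear points.
#' @return A list of class `circle_fit`: `center` (named x, y), `radius`,
#'   `residual` (RMS radial deviation), `n_points`.
#' @export
fit_circle_pratt <- function(points) {
  p <- as.matrix(as.data.frame(points)[, 1:2])
  p <- p[stats::complete.cases(p), , drop = FALSE]
  n <- nrow(p)
  if (n < 3L) {
    stop_handkin("circle fit needs at least 3 points", "handkin_fit_error")
  }
  cx0 <- mean(p[, 1L]); cy0 <- mean(p[, 2L])
  x <- p[, 1L] - cx0; y <- p[, 2L] - cy0
  sv <- svd(cbind(x, y))$d
  if (sv[2L] <= 1e-12 * max(sv[1L], 1)) {
    stop_handkin("points are collinear; no circle fit exists", "handkin_fit_error")
  }
  z <- x^2 + y^2
  Z <- cbind(z, x, y, 1)
  M <- crossprod(Z) / n
  B <- matrix(c(0, 0, 0, -2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                -2, 0, 0, 0), 4L, 4L)
  E <- eigen(solve(B, M))
  ev <- E$values
  real <- abs(Im(ev)) < 1e-8 * (abs(Re(ev)) + 1)
  ev_re <- Re(ev[real])
  vecs <- Re(E$vectors[, real, drop = FALSE])
  # Pratt solution: eigenvector of the smallest non-negative eigenvalue
  tol <- 1e-10 * max(abs(ev_re), 1)
  ok <- ev_re >= -tol
  if (!any(ok)) {
    stop_handkin("circle fit failed: no admissible eigenvalue", "handkin_fit_error")
  }
  A <- vecs[, which(ok)[which.min(ev_re[ok])]]
  if (abs(A[1L]) < 1e-14 * max(abs(A), 1)) {
    stop_handkin("points are collinear; no circle fit exists", "handkin_fit_error")
  }
  cx <- -A[2L] / (2 * A[1L])
  cy <- -A[3L] / (2 * A[1L])
  r2 <- (A[2L]^2 + A[3L]^2 - 4 * A[1L] * A[4L]) / (4 * A[1L]^2)
  if (!is.finite(r2) || r2 <= 0) {
    stop_handkin("circle fit failed: non-positive radius", "handkin_fit_error")
  }
  r <- sqrt(r2)
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(list(center = c(x = cx + cx0, y = cy + cy0), radius = r,
                 residual = sqrt(mean((d - r)^2)), n_points = n),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%.6g, %.6g), radius %.6g, RMS residual %.3g (n = %d)\n",
              x$center[1L], x$center[2L], x$radius, x$residual, x$n_points))
  invisible(x)
}

#' Head pitch angle from tracked eye positions
#'
#' When the head rotates in the sagittal plane, the tracked eye sweeps an
#' arc; the head angle per frame is the four-quadrant arctangent of the
#' eye's displacement from the center of the fitted circle. Image y is
#' converted to up-positive, so 0 deg points horizontally toward the
#' animal's front and positive angles are counterclockwise; head-down
#' postures are negative. The `flip` flag mirrors x, used for recordings
#' where the optics place the eye on the right of the circle center.
#'
#' @param eye two-column (x, y) matrix or data.frame of eye positions in
#'   image coordinates (y down).
#' @param fit a `circle_fit` from [fit_circle_pratt()].
#' @param flip if `TRUE`, negate the x displacement before the angle.
#' @return A data.frame with columns `frame` (0-based) and `theta_deg`
#'   (degrees in (-180, 180]; `NA` where the eye coincides with the center).
#' @export
head_angle_series <- function(eye, fit, flip = FALSE) {
  e <- as.matrix(as.data.frame(eye)[, 1:2])
  dx <- e[, 1L] - fit$center[[1L]]
  dy <- e[, 2L] - fit$center[[2L]]
  if (flip) dx <- -dx
  theta <- atan2(-dy, dx) * 180 / pi
  theta <- wrap_half_open(theta)
  theta[!is.na(dx) & !is.na(dy) & dx == 0 & dy == 0] <- NA_real_
  data.frame(frame = seq_len(nrow(e)) - 1L, theta_deg = theta)
}
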