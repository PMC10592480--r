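#' Pupil diameter from circumferential keypoints
#'
#' Algebraic least-squares circle fit (Kasa normal equations) to the
#' tracked pupil-edge keypoints of every frame; the diameter is twice the
#' fitted radius. The fit is invariant to translation and rotation of the
#' keypoints. Frames with fewer than 3 usable points or (near-)collinear
#' points are masked (`NA`).
#'
#' @param points frames x points x 2 array of (x, y) keypoints; `NA`
#'   entries mark untracked points.
#' @return numeric vector of diameters (pixels), `NA` where undefined.
#' @export
pupil_diameter <- function(points) {
  stopifnot(length(dim(points)) == 3L, dim(points)[3] == 2L)
  n <- dim(points)[1]
  out <- rep(NA_real_, n)
  warned <- FALSE
  for (i in seq_len(n)) {
    x <- points[i, , 1]; y <- points[i, , 2]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) { warned <- TRUE; next }
    x <- x[ok]; y <- y[ok]
    A <- cbind(2 * x, 2 * y, 1)
    b <- x^2 + y^2
    fit <- tryCatch(qr.solve(A, b, tol = 1e-10), error = function(e) NULL)
    if (is.null(fit)) { warned <- TRUE; next }
    r2 <- fit[3] + fit[1]^2 + fit[2]^2
    if (!is.finite(r2) || r2 <= 0) { warned <- TRUE; next }
    out[i] <- 2 * sqrt(r2)
  }
  if (warned) warning("frames with <3 usable or collinear keypoints were masked")
  out
}

#' Whisking speed from whisker keypoints
#'
#' Mean over keypoints of the per-point Euclidean displacement between
#' consecutive frames. The first frame is undefined (`NA`).
#'
#' @param points frames x points x 2 array of (x, y) whisker keypoints.
#' @return numeric vector of speeds (pixels/frame), `NA` at frame 1.
#' @export
whisk_speed <- function(points) {
  stopifnot(length(dim(points)) == 3L, dim(points)[3] == 2L)
  dx <- diff(points[, , 1, drop = FALSE][, , 1])
  dy <- diff(points[, , 2, drop = FALSE][, , 1])
  if (is.null(dim(dx))) { dx <- matrix(dx, ncol = 1L); dy <- matrix(dy, ncol = 1L) }
  c(NA_real_, rowMeans(sqrt(dx^2 + dy^2), na.rm = TRUE))
}

#' Wheel velocity from rotary-encoder counts
#'
#' First difference of the (unwrapped) count stream scaled to units per
#' second. Counter wraparound at a known modulus is handled so velocity is
#' continuous across the wrap.
#'
#' @param counts encoder counts per frame.
#' @param frame_rate Hz.
#' @param counts_per_unit calibration (counts per distance unit).
#' @param modulus optional counter modulus for wraparound handling.
#' @return velocity per frame (units/s); frame 1 repeats frame 2's value so
#'   the trace length-matches the imaging frames.
#' @export
wheel_velocity <- function(counts, frame_rate, counts_per_unit = 1, modulus = NULL) {
  d <- diff(counts)
  if (!is.null(modulus)) {
    d <- ((d + modulus / 2) %% modulus) - modulus / 2
  }
  v <- d * frame_rate / counts_per_unit
  c(v[1], v)
}

#' Read a keypoint table
#'
#' Long-format CSV with columns `frame`, `point_id`, `x`, `y` and an
#' optional `likelihood`; points below the likelihood threshold are masked.
#'
#' @param path CSV path.
#' @param likelihood_threshold minimum tracking confidence (default 0.9).
#' @return frames x points x 2 array suitable for [pupil_diameter()] /
#'   [whisk_speed()].
#' @export
read_keypoints <- function(path, likelihood_threshold = 0.9) {
  d <- utils::read.csv(path)
  frames <- sort(unique(d$frame)); pts <- sort(unique(d$point_id))
  out <- array(NA_real_, c(length(frames), length(pts), 2L))
  fi <- match(d$frame, frames); pi_ <- match(d$point_id, pts)
  keep <- if ("likelihood" %in% names(d)) d$likelihood >= likelihood_threshold
          else rep(TRUE, nrow(d))
  out[cbind(fi[keep], pi_[keep], 1L)] <- d$x[keep]
  out[cbind(fi[keep], pi_[keep], 2L)] <- d$y[keep]
  out
}

#' Downsample a behavioral trace to the imaging clock
#'
#' Behavioral cameras run faster than the imaging frame rate (60 vs 20
#' frames/s); traces are delivered at the imaging rate by averaging each
#' block of `factor` consecutive samples.
#'
#' @param x numeric vector at the camera rate.
#' @param factor integer decimation factor (default 3).
#' @return numeric vector of length `floor(length(x) / factor)`.
#' @export
downsample_behavior <- function(x, factor = 3L) {
  factor <- as.integer(factor)
  n <- (length(x) %/% factor) * factor
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}
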