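#' Moving-window correlation maps
#'
#' Computes the full pairwise Pearson correlation matrix of the ROI time
#' courses over a sliding temporal window (default 10 s, i.e. 200 samples
#' at 20 Hz), optionally removing a first-degree polynomial trend per ROI
#' within each window first (used for hemodynamic signals, whose slow
#' drifts would otherwise dominate short-window correlations).
#'
#' Windows are assigned to their central frame; the step between
#' consecutive windows defaults to a single frame so the coefficient time
#' courses downstream are effectively continuous.
#'
#' @param roi a [roi_matrix()].
#' @param window_s window length in seconds.
#' @param step_frames step between window starts, frames.
#' @param detrend remove a linear trend per ROI within each window.
#' @return object of class `corr_map_series`: `maps` (ROI x ROI x windows
#'   array), `starts`, `centers` (frame indices), `window_frames`,
#'   `window_s`, `step_frames`, `frame_rate`, `signal_kind`, and
#'   `zero_var_mask` flagging entries nulled because an ROI was constant
#'   within a window.
#' @export
windowed_correlation <- function(roi, window_s = 10, step_frames = 1L,
                                 detrend = FALSE) {
  x <- t(roi$values)                    # time x ROI
  n <- nrow(x); p <- ncol(x)
  w <- as.integer(round(window_s * roi$frame_rate))
  if (w > n) stop("window longer than the recording", call. = FALSE)
  if (w < 3L) stop("window must contain at least 3 samples", call. = FALSE)
  starts <- seq.int(1L, n - w + 1L, by = step_frames)
  nw <- length(starts)
  maps <- array(NA_real_, c(p, p, nw))
  Q <- NULL
  if (detrend) {
    Q <- qr.Q(qr(cbind(1, seq_len(w))))  # orthonormal [intercept, slope]
  }
  any_zero <- FALSE
  zv <- matrix(FALSE, p, nw)
  for (i in seq_len(nw)) {
    xw <- x[starts[i]:(starts[i] + w - 1L), , drop = FALSE]
    if (detrend) xw <- xw - Q %*% crossprod(Q, xw)
    sds <- apply(xw, 2L, stats::sd)
    bad <- sds == 0
    cm <- suppressWarnings(stats::cor(xw))
    if (any(bad)) {
      cm[bad, ] <- 0; cm[, bad] <- 0
      diag(cm) <- 1
      any_zero <- TRUE
      zv[bad, i] <- TRUE
    }
    maps[, , i] <- cm
  }
  if (any_zero)
    warning("zero-variance ROI(s) in some windows; affected entries set to 0")
  structure(list(maps = maps, starts = starts, centers = starts + w %/% 2L,
                 window_frames = w, window_s = window_s,
                 step_frames = as.integer(step_frames),
                 frame_rate = roi$frame_rate, signal_kind = roi$signal_kind,
                 zero_var_mask = zv),
            class = "corr_map_series")
}

#' @export
print.corr_map_series <- function(x, ...) {
  cat(sprintf("Correlation map series: %d x %d maps at %d windows (%g s window, step %d frames)\n",
              dim(x$maps)[1], dim(x$maps)[2], dim(x$maps)[3], x$window_s, x$step_frames))
  invisible(x)
}

#' Long-epoch correlation map
#'
#' One Pearson correlation map over the whole recording (or a frame
#' subset); maps from several epochs are averaged elementwise.
#'
#' @param roi a [roi_matrix()].
#' @param frames optional frame subset.
#' @return ROI x ROI correlation matrix.
#' @export
long_epoch_correlation <- function(roi, frames = NULL) {
  x <- t(roi$values)
  if (!is.null(frames)) x <- x[frames, , drop = FALSE]
  cm <- suppressWarnings(stats::cor(x))
  bad <- !is.finite(cm)
  if (any(bad)) { cm[bad] <- 0; diag(cm) <- 1
    warning("zero-variance ROI(s); affected entries set to 0") }
  cm
}

#' Trailing-window standard deviation
#'
#' Per-frame SD of each ROI over the preceding window (causal/trailing;
#' default 2 s), the local-variance measure used to track the suppression
#' of resting fluctuations around locomotion. Frames with an incomplete
#' window are `NA`.
#'
#' @param roi a [roi_matrix()].
#' @param window_s trailing window length in seconds.
#' @return ROI x time matrix of SDs (`NA` where undefined).
#' @export
windowed_sd <- function(roi, window_s = 2) {
  x <- roi$values
  w <- round(window_s * roi$frame_rate)
  if (w < 2L) stop("window must contain at least 2 samples", call. = FALSE)
  n <- ncol(x)
  kern <- rep(1, w)
  s1 <- t(apply(x, 1L, function(r) stats::filter(r, kern, sides = 1L)))
  s2 <- t(apply(x, 1L, function(r) stats::filter(r^2, kern, sides = 1L)))
  v <- (s2 - s1^2 / w) / (w - 1L)
  sqrt(pmax(v, 0))
}

#' Welch power spectral density
#'
#' One-sided PSD by Welch's method: Hann-windowed segments (default 4 s)
#' with 50% overlap, segment means removed, periodograms averaged. The
#' density integrates to the signal variance (Parseval).
#'
#' @param x numeric vector.
#' @param frame_rate sampling rate, Hz.
#' @param seg_s segment length, s.
#' @param overlap fractional overlap between segments.
#' @return data.frame with `freq` (Hz) and `power` (units^2/Hz).
#' @export
welch_psd <- function(x, frame_rate, seg_s = 4, overlap = 0.5) {
  n <- length(x)
  nseg <- round(seg_s * frame_rate)
  if (nseg > n) stop("segment longer than the signal", call. = FALSE)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  scale <- frame_rate * sum(win^2)
  nf <- nseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    P <- Mod(stats::fft(seg))^2 / scale
    acc <- acc + P[seq_len(nf)]
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]   # one-sided
  data.frame(freq = (seq_len(nf) - 1L) * frame_rate / nseg, power = psd)
}

#' Spectrogram (short-time Welch periodograms)
#'
#' @param x numeric vector.
#' @param frame_rate sampling rate, Hz.
#' @param seg_s segment length, s.
#' @param step_s step between segment starts, s.
#' @return list with `time` (segment centers, s), `freq` (Hz), and
#'   `power` (freq x time matrix).
#' @export
spectrogram <- function(x, frame_rate, seg_s = 4, step_s = 1) {
  n <- length(x)
  nseg <- round(seg_s * frame_rate)
  if (nseg > n) stop("segment longer than the signal", call. = FALSE)
  step <- max(1L, round(step_s * frame_rate))
  starts <- seq.int(1L, n - nseg + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))
  scale <- frame_rate * sum(win^2)
  nf <- nseg %/% 2L + 1L
  P <- matrix(NA_real_, nf, length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + nseg - 1L)]
    seg <- (seg - mean(seg)) * win
    pp <- Mod(stats::fft(seg))^2 / scale
    pp <- pp[seq_len(nf)]
    pp[2:(nf - 1L)] <- 2 * pp[2:(nf - 1L)]
    P[, i] <- pp
  }
  list(time = (starts + nseg / 2 - 1) / frame_rate,
       freq = (seq_len(nf) - 1L) * frame_rate / nseg, power = P)
}

#' Band-averaged spectral power
#'
#' @param psd data.frame from [welch_psd()].
#' @param band c(low, high) in Hz.
#' @return mean power within the band.
#' @export
band_average <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins", call. = FALSE)
  mean(psd$power[sel])
}

#' FFT band-pass filtering of ROI signals
#'
#' Zero-means each ROI trace and applies an ideal (FFT-domain) band-pass.
#'
#' @param roi a [roi_matrix()].
#' @param band c(low, high) in Hz, inside (0, Nyquist\].
#' @return a [roi_matrix()] of the band-limited signals.
#' @export
fft_bandpass <- function(roi, band) {
  fr <- roi$frame_rate
  if (band[1] < 0 || band[2] <= band[1] || band[1] >= fr / 2)
    stop("invalid frequency band", call. = FALSE)
  x <- roi$values
  n <- ncol(x)
  xc <- x - rowMeans(x)
  f <- (seq_len(n) - 1) * fr / n
  f <- pmin(f, fr - f)
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) stop("band contains no frequency bins", call. = FALSE)
  X <- stats::mvfft(t(xc))
  y <- t(Re(stats::mvfft(X * keep, inverse = TRUE)) / n)
  roi_matrix(y, frame_rate = fr, signal_kind = roi$signal_kind, roi_ids = roi$roi_ids)
}

#' Band-resolved correlation maps
#'
#' FFT band-pass filters the ROI signals per band, then computes a
#' correlation map per band, either over the full recording or as the mean
#' of 10-s window maps over a supplied window set (e.g. sustained-rest
#' windows), enabling the comparison of interregional correlation structure
#' across frequency bands.
#'
#' @param roi a [roi_matrix()].
#' @param bands list of c(low, high) Hz ranges.
#' @param windows optional data.frame with `start` frame indices of 10-s
#'   windows (as produced by [extract_state_windows()]).
#' @param window_s window length when `windows` is supplied.
#' @return named list of ROI x ROI correlation maps, one per band.
#' @export
band_filtered_maps <- function(roi, bands, windows = NULL, window_s = 10) {
  if (!length(bands)) stop("no bands supplied", call. = FALSE)
  out <- lapply(bands, function(b) {
    rb <- fft_bandpass(roi, b)
    if (is.null(windows)) {
      long_epoch_correlation(rb)
    } else {
      w <- round(window_s * roi$frame_rate)
      ms <- lapply(windows$start, function(s)
        long_epoch_correlation(rb, frames = s:(s + w - 1L)))
      Reduce(`+`, ms) / length(ms)
    }
  })
  names(out) <- vapply(bands, function(b) paste0(b[1], "-", b[2], "Hz"), character(1))
  out
}

#' Distance between two correlation maps
#'
#' Computed on the strict upper triangle (the diagonal is identically 1):
#' `euclidean` is the Frobenius norm of the difference over the upper
#' triangle; `correlation` is the Pearson correlation of the vectorized
#' upper triangles.
#'
#' @param map_a,map_b square matrices of identical shape.
#' @param metric `"euclidean"` or `"correlation"`.
#' @return scalar distance (or similarity, for `"correlation"`).
#' @export
map_distance <- function(map_a, map_b, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (!all(dim(map_a) == dim(map_b))) stop("maps differ in shape", call. = FALSE)
  a <- upper_tri_vec(map_a); b <- upper_tri_vec(map_b)
  switch(metric,
         euclidean = sqrt(sum((a - b)^2)),
         correlation = stats::cor(a, b))
}
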