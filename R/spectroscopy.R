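#' Select a resting baseline and form baseline images
#'
#' Finds the first run of `n_frames` consecutive frames whose wheel velocity
#' stays below `threshold` and averages each raw channel over those frames.
#' These baseline images define the normalization for the Beer-Lambert
#' conversion and the fluorescence correction.
#'
#' @param raw a `raw_session` (see [render_raw()]): list with `fluor_raw`,
#'   `green_raw`, `red_raw` pixel-by-time matrices and `behavior`.
#' @param wheel_velocity optional velocity trace; defaults to the session's.
#' @param threshold rest threshold on `|velocity|`; default 5% of the 99th
#'   percentile of the session's speed.
#' @param n_frames number of consecutive rest frames to average (default 100).
#' @return list with `fluor`, `green`, `red` baseline vectors (one value per
#'   pixel) and `frames`, the frame range used.
#' @export
select_baseline <- function(raw, wheel_velocity = NULL, threshold = NULL,
                            n_frames = 100L) {
  v <- wheel_velocity %||% raw$behavior$wheel_velocity
  if (is.null(v)) stop("no wheel velocity available", call. = FALSE)
  if (is.null(threshold)) threshold <- 0.05 * stats::quantile(abs(v), 0.99, names = FALSE)
  at_rest <- abs(v) <= threshold
  r <- rle(at_rest)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= n_frames)
  if (!length(ok))
    stop("no run of ", n_frames, " consecutive rest frames below threshold ",
         signif(threshold, 3), "; consider relaxing the threshold", call. = FALSE)
  start <- ends[ok[1]] - r$lengths[ok[1]] + 1L
  idx <- start:(start + n_frames - 1L)
  list(fluor = rowMeans(raw$fluor_raw[, idx, drop = FALSE]),
       green = rowMeans(raw$green_raw[, idx, drop = FALSE]),
       red   = rowMeans(raw$red_raw[, idx, drop = FALSE]),
       frames = range(idx))
}

## Divide each channel by its baseline image (pixel-wise).
normalize_session <- function(raw, baseline = NULL) {
  b <- baseline %||% select_baseline(raw)
  if (any(b$fluor <= 0) || any(b$green <= 0) || any(b$red <= 0))
    stop("baseline images must be strictly positive", call. = FALSE)
  list(fluor_norm = raw$fluor_raw / b$fluor,
       green_norm = raw$green_raw / b$green,
       red_norm   = raw$red_raw / b$red,
       frame_rate = raw$frame_rate, baseline = b)
}

#' Convert normalized reflectance to hemoglobin concentration changes
#'
#' Modified Beer-Lambert inversion: for each pixel and frame the normalized
#' reflectance at wavelength \eqn{\lambda} satisfies
#' \eqn{-\ln I^{norm}_R(t,\lambda) =
#'   (\epsilon_{HbO}(\lambda)\Delta[HbO] +
#'    \epsilon_{HbR}(\lambda)\Delta[HbR])\, X_R(\lambda)},
#' a 2x2 linear system across the green and red wavelengths solved for
#' \eqn{\Delta[HbO]} and \eqn{\Delta[HbR]} (uM); \eqn{\Delta[HbT]} is their
#' sum by definition.
#'
#' @param green_norm,red_norm baseline-normalized reflectance, pixel (or ROI)
#'   by time matrices, strictly positive.
#' @param optics an [optical_model()].
#' @param frame_rate sampling rate (Hz), carried through.
#' @return object of class `hemo_series`: list with `d_hbo`, `d_hbr`,
#'   `d_hbt` (uM) and `frame_rate`.
#' @export
convert_hemoglobin <- function(green_norm, red_norm, optics, frame_rate = NULL) {
  g <- as.matrix(green_norm); r <- as.matrix(red_norm)
  if (!all(dim(g) == dim(r))) stop("reflectance channels must share shape", call. = FALSE)
  bad <- which(g <= 0 | r <= 0)
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(g))
    stop(sprintf("nonpositive normalized reflectance at pixel %d, frame %d",
                 ij[1], ij[2]), call. = FALSE)
  }
  lg <- -log(g); lr <- -log(r)
  Minv <- optics$Minv
  d_hbo <- Minv[1, 1] * lg + Minv[1, 2] * lr
  d_hbr <- Minv[2, 1] * lg + Minv[2, 2] * lr
  structure(list(d_hbo = d_hbo, d_hbr = d_hbr, d_hbt = d_hbo + d_hbr,
                 frame_rate = frame_rate),
            class = "hemo_series")
}

#' Correct raw fluorescence for time-varying hemoglobin absorption
#'
#' Both the excitation light on its way to the fluorophore and the emitted
#' fluorescence on its way out are attenuated by hemoglobin. Because the
#' green reflectance experiences (approximately) the excitation-band
#' absorption and the red reflectance the emission-band absorption, the
#' correction divides the normalized fluorescence by powers of the two
#' normalized reflectances:
#' \deqn{\frac{F(t)}{F(base)} =
#'   \frac{I^{norm}_{em}(t)}{I^{norm}_R(t,\lambda_{red})^{P_r}\,
#'         I^{norm}_R(t,\lambda_{green})^{P_g}}}
#' and reports `dff` \eqn{= F(t)/F(base) - 1}.
#'
#' @param fluor_norm baseline-normalized raw fluorescence (pixel/ROI x time).
#' @param green_norm,red_norm baseline-normalized reflectance, positive.
#' @param Pg,Pr pathlength ratios; see [optical_model()].
#' @param frame_rate sampling rate (Hz), carried through.
#' @return object of class `fluor_series`: list with `dff` and `frame_rate`.
#' @export
correct_fluorescence <- function(fluor_norm, green_norm, red_norm, Pg, Pr,
                                 frame_rate = NULL) {
  f <- as.matrix(fluor_norm); g <- as.matrix(green_norm); r <- as.matrix(red_norm)
  if (!all(dim(f) == dim(g)) || !all(dim(f) == dim(r)))
    stop("all channels must share shape", call. = FALSE)
  if (any(g <= 0) || any(r <= 0))
    stop("normalized reflectance must be strictly positive", call. = FALSE)
  dff <- f * exp(-Pr * log(r) - Pg * log(g)) - 1
  structure(list(dff = dff, frame_rate = frame_rate), class = "fluor_series")
}

#' Estimate the pathlength ratios Pg and Pr by decorrelation
#'
#' The correction is judged by how well it removes vascular (hemodynamic)
#' structure from the corrected fluorescence. This estimator grid-searches
#' `(Pg, Pr)` minimizing the mean absolute Pearson correlation between the
#' corrected `dff` and the total-hemoglobin time course across pixels, a
#' quantitative proxy for the disappearance of vessel-like artifacts.
#'
#' @param raw a `raw_session`.
#' @param optics an [optical_model()] providing the extinction constants.
#' @param pg_grid,pr_grid search grids; defaults span \[0, 0.6\] and
#'   \[0.5, 2.5\], bracketing the plausible ranges.
#' @param baseline optional precomputed [select_baseline()] result.
#' @param max_pixels cap on the number of (evenly spaced) pixels used to
#'   evaluate the objective.
#' @return list with `Pg`, `Pr`, the `objective` matrix
#'   (rows `pg_grid`, columns `pr_grid`) and the grids.
#' @export
estimate_pathlength_ratios <- function(raw, optics,
                                       pg_grid = seq(0, 0.6, by = 0.05),
                                       pr_grid = seq(0.5, 2.5, by = 0.1),
                                       baseline = NULL, max_pixels = 400L) {
  nrm <- normalize_session(raw, baseline)
  if (stats::sd(nrm$green_norm) < 1e-12 && stats::sd(nrm$red_norm) < 1e-12)
    stop("session has no hemodynamic variation; objective undefined", call. = FALSE)
  npix <- nrow(nrm$fluor_norm)
  keep <- unique(round(seq(1L, npix, length.out = min(npix, max_pixels))))
  f <- nrm$fluor_norm[keep, , drop = FALSE]
  lg <- log(nrm$green_norm[keep, , drop = FALSE])
  lr <- log(nrm$red_norm[keep, , drop = FALSE])
  hemo <- convert_hemoglobin(exp(lg), exp(lr), optics)
  hbt <- hemo$d_hbt
  ## drop pixels whose hemodynamics are (numerically) constant
  ok <- apply(hbt, 1L, stats::sd) > 1e-12
  if (!any(ok)) stop("session has no hemodynamic variation; objective undefined", call. = FALSE)
  f <- f[ok, , drop = FALSE]; lg <- lg[ok, , drop = FALSE]
  lr <- lr[ok, , drop = FALSE]; hbt <- hbt[ok, , drop = FALSE]
  obj <- matrix(NA_real_, length(pg_grid), length(pr_grid),
                dimnames = list(Pg = pg_grid, Pr = pr_grid))
  for (i in seq_along(pg_grid)) {
    for (j in seq_along(pr_grid)) {
      dff <- f * exp(-pr_grid[j] * lr - pg_grid[i] * lg) - 1
      obj[i, j] <- mean(abs(rowwise_cor(dff, hbt)), na.rm = TRUE)
    }
  }
  best <- arrayInd(which.min(obj), dim(obj))
  list(Pg = pg_grid[best[1]], Pr = pr_grid[best[2]],
       objective = obj, pg_grid = pg_grid, pr_grid = pr_grid)
}
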