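#' ROI-by-time signal matrix
#'
#' Container for extracted region time courses. Row order follows the
#' bilaterally paired ROI order of the parcellation (left ROIs first, then
#' their right-hemisphere partners in the same sequence).
#'
#' @param values numeric ROI x time matrix.
#' @param frame_rate sampling rate in Hz.
#' @param signal_kind one of `"neural_dff"`, `"hbt"`, `"hbo"`, `"hbr"`,
#'   `"raw"`.
#' @param roi_ids optional ROI identifiers (default row sequence).
#' @return object of class `roi_matrix`.
#' @export
roi_matrix <- function(values, frame_rate,
                       signal_kind = c("neural_dff", "hbt", "hbo", "hbr", "raw"),
                       roi_ids = NULL) {
  values <- as.matrix(values)
  signal_kind <- match.arg(signal_kind)
  stopifnot_scalar_pos(frame_rate, "frame_rate")
  roi_ids <- roi_ids %||% seq_len(nrow(values))
  structure(list(values = values, roi_ids = roi_ids,
                 frame_rate = frame_rate, signal_kind = signal_kind),
            class = "roi_matrix")
}

#' @export
print.roi_matrix <- function(x, ...) {
  cat(sprintf("ROI matrix: %d ROIs x %d frames at %g Hz (%s)\n",
              nrow(x$values), ncol(x$values), x$frame_rate, x$signal_kind))
  invisible(x)
}

#' Remove global pulsation from an image stack
#'
#' Divides every frame by one plus the temporally high-pass-filtered
#' fractional fluctuation of the spatially uniform (global mean) component,
#' suppressing heart-rate-band intensity modulation that is shared across
#' the field of view while leaving spatially structured, slower signals
#' untouched. Typical cutoffs: above 1 Hz for reflectance (hemodynamic)
#' channels, above 2 Hz for the fluorescence (neural) channel.
#'
#' @param stack pixel x time matrix, strictly positive.
#' @param cutoff_hz high-pass cutoff for the global component.
#' @param frame_rate sampling rate in Hz.
#' @param order filter order for the global-component high-pass.
#' @return stack with the global pulsation removed.
#' @export
remove_global_pulsation <- function(stack, cutoff_hz, frame_rate, order = 6L) {
  stack <- as.matrix(stack)
  g <- colMeans(stack)
  if (any(g <= 0)) stop("global mean must be strictly positive", call. = FALSE)
  frac <- g / mean(g) - 1
  h <- zero_phase_filter(frac, filter_spec("highpass", cutoff_hz, order = order),
                         frame_rate)
  denom <- 1 + h
  if (any(denom <= 0)) stop("global pulsation exceeds 100%; cannot divide", call. = FALSE)
  sweep(stack, 2L, denom, "/")
}

#' Denoise an image stack by truncated PCA
#'
#' Rank-`n_components` reconstruction of the mean-centered pixel x time
#' matrix via truncated SVD, with the pixel means restored. At full
#' acquisition scale 200 components are retained for reflectance channels
#' and 300 for the fluorescence channel; the counts scale down with data
#' size (they are elbow choices, not constants of nature).
#'
#' @param stack pixel x time matrix.
#' @param n_components number of spatiotemporal components to retain.
#' @return denoised stack, same shape.
#' @export
pca_denoise <- function(stack, n_components) {
  stack <- as.matrix(stack)
  k <- as.integer(n_components)
  if (k < 1L) stop("'n_components' must be >= 1", call. = FALSE)
  if (k > min(dim(stack)))
    stop("'n_components' exceeds min(pixels, frames)", call. = FALSE)
  mu <- rowMeans(stack)
  xc <- stack - mu
  sv <- svd(xc, nu = k, nv = k)
  rec <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v))
  rec + mu
}

#' Extract per-ROI average time courses
#'
#' Unweighted mean over member pixels for every ROI of a parcellation,
#' one row per ROI in the parcellation's paired order. Extracting from raw
#' channels before conversion reduces the influence of small motion
#' artifacts on single pixels.
#'
#' @param stack pixel x time matrix; rows must correspond to the pixels of
#'   the label image in column-major order.
#' @param parcellation a `parcellation_map` (see [mirror_and_pair()]) or a
#'   label vector/matrix (0 = background).
#' @param frame_rate,signal_kind metadata for the returned [roi_matrix()].
#' @return a [roi_matrix()].
#' @export
extract_roi_timecourses <- function(stack, parcellation, frame_rate = 20,
                                    signal_kind = "raw") {
  labels <- if (inherits(parcellation, "parcellation_map")) parcellation$labels
            else parcellation
  labels <- as.integer(labels)
  stack <- as.matrix(stack)
  if (length(labels) != nrow(stack))
    stop("label image does not match the stack's pixel count", call. = FALSE)
  ids <- sort(unique(labels[labels > 0L]))
  expected <- seq_len(max(ids))
  missing <- setdiff(expected, ids)
  if (length(missing))
    stop("empty ROI(s): ", paste(missing, collapse = ", "), call. = FALSE)
  inmask <- labels > 0L
  sums <- rowsum(stack[inmask, , drop = FALSE], labels[inmask])
  counts <- tabulate(labels[inmask], nbins = max(ids))
  roi_matrix(sums / counts, frame_rate = frame_rate, signal_kind = signal_kind,
             roi_ids = ids)
}
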