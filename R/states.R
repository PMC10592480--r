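## canonical order of the five behavioral correlation states
state_names <- function() {
  c("onset", "locomotion", "offset", "initial_rest", "sustained_rest")
}

#' Detect locomotion bouts from wheel velocity
#'
#' Supra-threshold runs of the wheel velocity; runs separated by less than
#' `min_gap_s` are merged into one bout. Each bout carries its duration and
#' the rest (quiescence) durations before and after it, measured to the
#' neighboring bouts or the record edges.
#'
#' @param wheel_velocity velocity trace at the imaging frame rate.
#' @param frame_rate Hz.
#' @param threshold velocity threshold; default 5% of the 99th percentile
#'   of the session's speed.
#' @param min_gap_s sub-threshold gaps shorter than this are absorbed.
#' @return data.frame of class `locomotion_bouts` with `onset`, `offset`
#'   (1-based frame indices, half-open `[onset, offset)`), `duration_s`,
#'   `pre_rest_s`, `post_rest_s`; the threshold used is attached as an
#'   attribute.
#' @export
detect_bouts <- function(wheel_velocity, frame_rate, threshold = NULL,
                         min_gap_s = 1) {
  v <- abs(wheel_velocity)
  if (is.null(threshold)) threshold <- 0.05 * stats::quantile(v, 0.99, names = FALSE)
  b <- runs_to_bouts(v > threshold, frame_rate)
  if (nrow(b) > 1L) {
    gap <- (b$onset[-1L] - b$offset[-nrow(b)]) / frame_rate
    keep_new <- c(TRUE, gap >= min_gap_s)
    grp <- cumsum(keep_new)
    b <- data.frame(onset = tapply(b$onset, grp, min),
                    offset = tapply(b$offset, grp, max))
    b$duration_s <- (b$offset - b$onset) / frame_rate
    n <- length(wheel_velocity)
    b$pre_rest_s <- (b$onset - c(1L, b$offset[-nrow(b)])) / frame_rate
    b$post_rest_s <- (c(b$onset[-1L], n + 1L) - b$offset) / frame_rate
    rownames(b) <- NULL
  }
  structure(b, class = c("locomotion_bouts", "data.frame"), threshold = threshold)
}

#' Extract the temporal windows defining the five behavioral states
#'
#' For each locomotion bout, 10-s windows are selected by the state
#' definitions:
#' \itemize{
#'   \item onset: window overlapping 5 s rest and 5 s locomotion, for bouts
#'     of at least 10 s duration with at least 60 s pre-locomotion rest;
#'   \item locomotion: the 10 s in the middle of the bout, for bouts of at
#'     least 20 s duration;
#'   \item offset: 5 s locomotion + 5 s rest, for bouts of at least 20 s
#'     duration with at least 10 s post-locomotion rest;
#'   \item initial rest: the first 10 s immediately after locomotion
#'     cessation, for bouts lasting at least 5 s with at least 60 s
#'     post-locomotion rest;
#'   \item sustained rest: the 10 s starting 40 s after locomotion
#'     cessation, for the same bouts as initial rest.
#' }
#' A bout may contribute to several states. Windows extending beyond the
#' recording are dropped.
#'
#' @param bouts a [detect_bouts()] table.
#' @param frame_rate Hz.
#' @param n_frames recording length in frames.
#' @param window_s window length (default 10 s).
#' @return data.frame with `state`, `start`, `end` (half-open frame
#'   indices), `bout_id`.
#' @export
extract_state_windows <- function(bouts, frame_rate, n_frames, window_s = 10) {
  w <- round(window_s * frame_rate)
  h <- w %/% 2L
  rows <- list()
  add <- function(state, start, b) {
    if (start >= 1L && start + w - 1L <= n_frames)
      rows[[length(rows) + 1L]] <<- data.frame(state = state, start = start,
                                               end = start + w, bout_id = b)
  }
  for (b in seq_len(nrow(bouts))) {
    on <- bouts$onset[b]; off <- bouts$offset[b]
    dur <- bouts$duration_s[b]; pre <- bouts$pre_rest_s[b]; post <- bouts$post_rest_s[b]
    if (dur >= 10 && pre >= 60) add("onset", on - h, b)
    if (dur >= 20) add("locomotion", on + round((off - on) / 2) - h, b)
    if (dur >= 20 && post >= 10) add("offset", off - h, b)
    if (dur >= 5 && post >= 60) {
      add("initial_rest", off, b)
      add("sustained_rest", off + round(40 * frame_rate), b)
    }
  }
  if (!length(rows))
    return(data.frame(state = character(), start = integer(),
                      end = integer(), bout_id = integer()))
  out <- do.call(rbind, rows)
  out$state <- factor(out$state, levels = state_names())
  out
}

#' Detect rest epochs
#'
#' Contiguous sub-threshold (quiescent) periods of at least
#' `min_duration_s`, the epochs over which resting-state reciprocity and
#' arousal associations are evaluated.
#'
#' @inheritParams detect_bouts
#' @param min_duration_s minimum epoch length (default 60 s).
#' @return data.frame with `start`, `end` (half-open), `duration_s`.
#' @export
detect_rest_epochs <- function(wheel_velocity, frame_rate, threshold = NULL,
                               min_duration_s = 60) {
  v <- abs(wheel_velocity)
  if (is.null(threshold)) threshold <- 0.05 * stats::quantile(v, 0.99, names = FALSE)
  r <- rle(v <= threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- which(r$values & r$lengths >= round(min_duration_s * frame_rate))
  data.frame(start = starts[sel], end = ends[sel] + 1L,
             duration_s = r$lengths[sel] / frame_rate)
}

## map window starts onto indices of a corr_map_series: exact at step 1,
## otherwise snapped to the nearest covered window (within half a step)
series_index_of_start <- function(corr_series, start) {
  step <- corr_series$step_frames
  idx <- round((start - corr_series$starts[1]) / step) + 1
  off <- abs(start - corr_series$starts[pmin(pmax(idx, 1), length(corr_series$starts))])
  if (any(idx < 1 | idx > length(corr_series$starts) | off > step / 2))
    stop("window not covered by the correlation map series", call. = FALSE)
  as.integer(idx)
}

#' Build the five-state correlation basis
#'
#' Elementwise mean of the windowed correlation maps over the temporal
#' windows of each state.
#'
#' @param corr_series a [windowed_correlation()] result.
#' @param windows an [extract_state_windows()] table.
#' @return object of class `state_basis`: `maps` (ROI x ROI x 5 array in
#'   state order), `n_windows` per state, `source_windows`.
#' @export
build_state_basis <- function(corr_series, windows) {
  sts <- state_names()
  counts <- table(factor(windows$state, levels = sts))
  if (any(counts == 0L))
    stop("no windows for state(s): ",
         paste(sts[counts == 0L], collapse = ", "), call. = FALSE)
  p <- dim(corr_series$maps)[1]
  maps <- array(NA_real_, c(p, p, length(sts)), dimnames = list(NULL, NULL, sts))
  for (s in sts) {
    idx <- series_index_of_start(corr_series, windows$start[windows$state == s])
    maps[, , s] <- apply(corr_series$maps[, , idx, drop = FALSE], c(1, 2), mean)
  }
  structure(list(maps = maps, n_windows = as.integer(counts),
                 source_windows = windows),
            class = "state_basis")
}

#' @export
print.state_basis <- function(x, ...) {
  cat("State basis:", paste(sprintf("%s (%d)", state_names(), x$n_windows),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Decompose windowed correlation maps into behavioral states
#'
#' Models every real-time (moving-window) correlation map `d` as a
#' non-negative linear combination of the five behavioral correlation-state
#' basis maps `x_1..x_5`, \eqn{d = \sum_n x_n c_n}, solving for the
#' coefficients by non-negative least squares on the vectorized strict
#' upper triangles. The goodness of fit per window is
#' \eqn{\|(d - cx)^2\|_1 / \|d^2\|_1} (0 = perfect).
#'
#' With `cv_folds > 1` the fit is cross-validated at the bout level:
#' locomotion bouts contributing basis windows are partitioned into folds,
#' and any map window overlapping a basis window is fit against a basis
#' rebuilt without that bout's fold, so no window is fit against a basis it
#' helped define. Windows overlapping no basis window use the full basis.
#'
#' @param corr_series a [windowed_correlation()] result.
#' @param basis optional [build_state_basis()] result (required when
#'   `cv_folds <= 1`).
#' @param windows the [extract_state_windows()] table (required for
#'   cross-validation; defaults to `basis$source_windows`).
#' @param cv_folds number of cross-validation folds over bouts (default 5).
#' @param seed seed for the fold partition.
#' @return object of class `state_fit` with `coefficients` (5 x windows,
#'   nonnegative), `residual`, `centers`, the full-data `basis`, and fold
#'   bookkeeping.
#' @export
fit_states_nnls <- function(corr_series, basis = NULL, windows = NULL,
                            cv_folds = 5L, seed = NULL) {
  windows <- windows %||% basis$source_windows
  if (is.null(basis)) {
    if (is.null(windows)) stop("need 'basis' or 'windows'", call. = FALSE)
    basis <- build_state_basis(corr_series, windows)
  }
  sts <- state_names()
  p <- dim(corr_series$maps)[1]
  nw <- dim(corr_series$maps)[3]
  ut <- function(a) apply(a, 3L, upper_tri_vec)
  D <- ut(corr_series$maps)                       # nut x nw
  Xfull <- ut(basis$maps)                         # nut x 5
  if (qr(Xfull)$rank < ncol(Xfull))
    warning("state basis maps are not linearly independent on the upper triangle")
  fold_of_window <- integer(nw)                   # 0 = full basis
  bases <- list()
  cv_folds <- as.integer(cv_folds)
  if (cv_folds > 1L && !is.null(windows) && nrow(windows)) {
    bout_ids <- sort(unique(windows$bout_id))
    k <- min(cv_folds, length(bout_ids))
    if (!is.null(seed)) set.seed(seed)
    fold_of_bout <- sample(rep_len(seq_len(k), length(bout_ids)))
    names(fold_of_bout) <- bout_ids
    ## assign each map window the fold of the basis window it overlaps
    w <- corr_series$window_frames
    for (i in seq_len(nrow(windows))) {
      ov <- corr_series$starts < windows$end[i] &
            corr_series$starts + w > windows$start[i]
      fold_of_window[ov] <- fold_of_bout[as.character(windows$bout_id[i])]
    }
    for (f in seq_len(k)) {
      keep <- windows[fold_of_bout[as.character(windows$bout_id)] != f, , drop = FALSE]
      maps_f <- array(NA_real_, dim(basis$maps), dimnames = dimnames(basis$maps))
      for (s in sts) {
        idx <- series_index_of_start(corr_series, keep$start[keep$state == s])
        if (!length(idx)) {
          warning("state '", s, "' has no windows outside fold ", f,
                  "; using the full-data state map")
          maps_f[, , s] <- basis$maps[, , s]
        } else {
          maps_f[, , s] <- apply(corr_series$maps[, , idx, drop = FALSE], c(1, 2), mean)
        }
      }
      bases[[f]] <- ut(maps_f)
    }
  }
  coefs <- matrix(0, length(sts), nw, dimnames = list(sts, NULL))
  resid <- numeric(nw)
  for (f in sort(unique(fold_of_window))) {
    X <- if (f == 0L) Xfull else bases[[f]]
    XtX <- crossprod(X)
    sel <- which(fold_of_window == f)
    XtD <- crossprod(X, D[, sel, drop = FALSE])
    for (j in seq_along(sel)) {
      d2 <- sum(D[, sel[j]]^2)
      if (d2 == 0) { resid[sel[j]] <- 1; next }
      cc <- nnls_from_cross(XtX, XtD[, j])
      coefs[, sel[j]] <- cc
      resid[sel[j]] <- (d2 - 2 * sum(cc * XtD[, j]) +
                          drop(crossprod(cc, XtX %*% cc))) / d2
    }
  }
  structure(list(coefficients = coefs, residual = pmax(resid, 0),
                 centers = corr_series$centers, starts = corr_series$starts,
                 window_frames = corr_series$window_frames,
                 frame_rate = corr_series$frame_rate,
                 signal_kind = corr_series$signal_kind,
                 basis = basis, n_roi = p,
                 cv = list(folds = length(bases), fold_of_window = fold_of_window)),
            class = "state_fit")
}

#' @export
print.state_fit <- function(x, ...) {
  cat(sprintf("Behavioral correlation-state decomposition (%s signal)\n", x$signal_kind))
  cat(sprintf("  %d windows of %d frames, %d ROIs; %s\n",
              length(x$residual), x$window_frames, x$n_roi,
              if (x$cv$folds > 0) sprintf("%d-fold cross-validated", x$cv$folds)
              else "no cross-validation"))
  cat(sprintf("  median residual %.3f; mean coefficients: %s\n",
              stats::median(x$residual),
              paste(sprintf("%s %.2f", rownames(x$coefficients),
                            rowMeans(x$coefficients)), collapse = ", ")))
  invisible(x)
}

#' @export
summary.state_fit <- function(object, ...) {
  co <- object$coefficients
  out <- list(
    states = data.frame(state = rownames(co), mean = rowMeans(co),
                        sd = apply(co, 1L, stats::sd),
                        argmax_share = tabulate(apply(co, 2L, which.max),
                                                nrow(co)) / ncol(co)),
    residual = stats::quantile(object$residual, c(0.05, 0.25, 0.5, 0.75, 0.95)),
    n_windows = ncol(co), cv_folds = object$cv$folds)
  class(out) <- "summary.state_fit"
  out
}

#' @export
print.summary.state_fit <- function(x, ...) {
  cat(sprintf("State fit over %d windows (%s)\n", x$n_windows,
              if (x$cv_folds > 0) sprintf("%d-fold CV", x$cv_folds) else "no CV"))
  print(x$states, row.names = FALSE, digits = 3)
  cat("Residual quantiles:\n"); print(signif(x$residual, 3))
  invisible(x)
}

#' @export
coef.state_fit <- function(object, ...) object$coefficients

#' @export
residuals.state_fit <- function(object, ...) object$residual

#' Reconstruct correlation maps from a state fit
#'
#' @param object a [fit_states_nnls()] result.
#' @param windows window indices (default all).
#' @param as_maps return full symmetric matrices (array) instead of
#'   upper-triangle vectors.
#' @param ... unused.
#' @return upper-triangle matrix (entries x windows) or ROI x ROI x windows
#'   array.
#' @export
predict.state_fit <- function(object, windows = NULL, as_maps = FALSE, ...) {
  windows <- windows %||% seq_along(object$residual)
  X <- apply(object$basis$maps, 3L, upper_tri_vec)
  V <- X %*% object$coefficients[, windows, drop = FALSE]
  if (!as_maps) return(V)
  p <- object$n_roi
  out <- array(NA_real_, c(p, p, length(windows)))
  for (i in seq_along(windows)) out[, , i] <- vec_to_corr_map(V[, i], p)
  out
}

#' @export
fitted.state_fit <- function(object, ...) predict(object)

#' Plot state coefficient time courses
#'
#' @param x a `state_fit`.
#' @param states which states to draw (default all five).
#' @param ... passed to [graphics::matplot()].
#' @export
plot.state_fit <- function(x, states = state_names(), ...) {
  t_s <- x$centers / x$frame_rate
  co <- t(x$coefficients[states, , drop = FALSE])
  graphics::matplot(t_s, co, type = "l", lty = 1,
                    xlab = "time (s)", ylab = "state coefficient", ...)
  graphics::legend("topright", legend = states, lty = 1,
                   col = seq_along(states), bty = "n", cex = 0.8)
  invisible(x)
}

#' Event-aligned average state coefficients
#'
#' Aligns the coefficient time courses of every qualifying bout to its
#' locomotion onset (or offset) and averages across bouts, reporting mean
#' and SEM per state at each event-relative time; time 0 is the event
#' frame.
#'
#' @param fit a [fit_states_nnls()] result.
#' @param bouts a [detect_bouts()] table.
#' @param mode align to `"onset"` or `"offset"`.
#' @param span_s c(before, after) in seconds relative to the event.
#' @return list with `time_s`, `mean` (state x time), `sem`, `n_bouts`.
#' @export
align_coefficients <- function(fit, bouts, mode = c("onset", "offset"),
                               span_s = c(-10, 20)) {
  mode <- match.arg(mode)
  if (!nrow(bouts)) stop("need at least one bout", call. = FALSE)
  fr <- fit$frame_rate
  rel <- seq.int(round(span_s[1] * fr), round(span_s[2] * fr))
  events <- bouts[[mode]]
  sts <- rownames(fit$coefficients)
  acc <- array(NA_real_, c(length(sts), length(rel), length(events)))
  first_center <- fit$centers[1]
  step <- fit$starts[2] - fit$starts[1]
  for (b in seq_along(events)) {
    frames <- events[b] + rel
    idx <- (frames - first_center) / step + 1
    ok <- idx == round(idx) & idx >= 1 & idx <= ncol(fit$coefficients)
    acc[, ok, b] <- fit$coefficients[, idx[ok]]
  }
  m <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  n_eff <- apply(!is.na(acc[1, , , drop = FALSE]), 2, sum)
  s <- apply(acc, c(1, 2), stats::sd, na.rm = TRUE) /
    sqrt(pmax(matrix(n_eff, length(sts), length(rel), byrow = TRUE), 1))
  s[, n_eff <= 1] <- 0
  dimnames(m) <- list(sts, NULL); dimnames(s) <- list(sts, NULL)
  list(time_s = rel / fr, mean = m, sem = s, n_bouts = length(events))
}

#' Reciprocity of the two resting states
#'
#' Pearson correlation, per rest epoch, between the initial-rest and
#' sustained-rest coefficients. A strongly negative value indicates that
#' the two rest states trade off against one another as arousal wanes and
#' waxes during prolonged quiescence.
#'
#' @param fit a [fit_states_nnls()] result.
#' @param rest_epochs a [detect_rest_epochs()] table.
#' @return numeric vector, one correlation per epoch (`NA` where a
#'   coefficient was constant; such epochs are skipped with a warning).
#' @export
rest_reciprocity <- function(fit, rest_epochs) {
  out <- rep(NA_real_, nrow(rest_epochs))
  for (e in seq_len(nrow(rest_epochs))) {
    sel <- fit$centers >= rest_epochs$start[e] & fit$centers < rest_epochs$end[e]
    c4 <- fit$coefficients["initial_rest", sel]
    c5 <- fit$coefficients["sustained_rest", sel]
    if (sum(sel) < 3 || stats::sd(c4) == 0 || stats::sd(c5) == 0) {
      warning("epoch ", e, " skipped (constant coefficient)")
      next
    }
    out[e] <- stats::cor(c4, c5)
  }
  out
}

#' Association between resting-state coefficients and arousal
#'
#' Per rest epoch, Pearson correlations between each resting-state
#' coefficient and pupil diameter (the arousal index); the two resulting
#' correlation distributions are summarized by Epanechnikov kernel density
#' estimates and compared with a two-sample Kolmogorov-Smirnov test.
#'
#' @param fit a [fit_states_nnls()] result.
#' @param pupil pupil-diameter trace at the imaging frame rate.
#' @param rest_epochs a [detect_rest_epochs()] table.
#' @return list with `r_initial`, `r_sustained` (per-epoch correlations),
#'   `kde_initial`, `kde_sustained` ([epanechnikov_kde()] results) and
#'   `ks` ([ks_two_sample()] result).
#' @export
arousal_association <- function(fit, pupil, rest_epochs) {
  r4 <- rep(NA_real_, nrow(rest_epochs)); r5 <- r4
  for (e in seq_len(nrow(rest_epochs))) {
    sel <- fit$centers >= rest_epochs$start[e] & fit$centers < rest_epochs$end[e]
    if (sum(sel) < 3) next
    pp <- pupil[fit$centers[sel]]
    c4 <- fit$coefficients["initial_rest", sel]
    c5 <- fit$coefficients["sustained_rest", sel]
    if (stats::sd(pp) == 0) { warning("epoch ", e, " skipped (constant pupil)"); next }
    if (stats::sd(c4) > 0) r4[e] <- stats::cor(c4, pp)
    if (stats::sd(c5) > 0) r5[e] <- stats::cor(c5, pp)
  }
  ok4 <- r4[!is.na(r4)]; ok5 <- r5[!is.na(r5)]
  list(r_initial = r4, r_sustained = r5,
       kde_initial = if (length(ok4) >= 2) epanechnikov_kde(ok4) else NULL,
       kde_sustained = if (length(ok5) >= 2) epanechnikov_kde(ok5) else NULL,
       ks = if (length(ok4) && length(ok5)) ks_two_sample(ok4, ok5) else NULL)
}
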