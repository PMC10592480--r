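#' Configuration for the synthetic session generator
#'
#' The generator emulates the statistical structure the pipeline assumes of
#' a wide-field optical mapping session: parcel-structured neural dynamics
#' with high-amplitude band-limited resting fluctuations in anterior
#' parcels that locomotion suppresses, locomotion-locked sensory
#' activation, bilateral parcel symmetry, arousal-state switching during
#' rest, gamma-HRF neurovascular coupling with a delay, cardiac/respiratory
#' oscillations on the hemodynamic signals, and behavior (locomotion bouts,
#' slow exponential pupil decay after locomotion offset, whisking).
#'
#' @param frame_rate imaging frame rate per channel, Hz.
#' @param duration_s session length, s.
#' @param image_shape c(rows, cols) in pixels.
#' @param n_parcels_per_hemisphere parcel count per hemisphere (8 in tests,
#'   46 for full-scale emulation).
#' @param midline_gap width of the midline gap, pixels.
#' @param bout_rate_per_min expected locomotion bouts per minute.
#' @param bout_duration_range uniform range of bout durations, s.
#' @param rest_band_hz frequency band of resting fluctuations, Hz.
#' @param rest_gain_anterior amplitude gain of anterior resting
#'   fluctuations relative to other parcels (dimensionless; free parameter
#'   of the emulation).
#' @param locomotion_suppression multiplicative suppression of anterior
#'   fluctuations during locomotion, in (0, 1).
#' @param bilateral_r target Pearson correlation of bilateral parcel pairs.
#' @param hrf list(shape, scale, amplitude): gamma hemodynamic response
#'   kernel parameters (scale in s) and coupling amplitude in uM total
#'   hemoglobin per unit neural drive.
#' @param hrf_lag_s pure neurovascular delay, s.
#' @param pupil_decay_tau_s time constant of the post-locomotion pupil
#'   (arousal) decay, s; ~15 s returns the pupil to baseline about 40 s
#'   after locomotion offset.
#' @param pupil_base_px,pupil_gain baseline pupil diameter (pixels) and
#'   fractional dilation at full arousal.
#' @param artifact_heart_hz,artifact_breath_hz cardiac and respiratory
#'   oscillation frequencies, Hz.
#' @param artifact_heart_uM,artifact_breath_uM their hemoglobin-equivalent
#'   amplitudes, uM.
#' @param dff_scale fluorescence modulation per unit neural drive
#'   (fractional dF/F).
#' @param pixel_noise_sd white pixel noise, in units of the (unit-variance)
#'   parcel signal.
#' @param channel_noise_sd named vector (fluor, green, red): multiplicative
#'   measurement noise per raw channel. Zero by default: photon noise is
#'   outside the emulation's scope and exact forward-inverse round trips
#'   are part of its contract.
#' @param seed integer seed; fully determines the session.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(frame_rate = 20,
                       duration_s = 600,
                       image_shape = c(60, 60),
                       n_parcels_per_hemisphere = 8L,
                       midline_gap = 2L,
                       bout_rate_per_min = 0.5,
                       bout_duration_range = c(10, 40),
                       rest_band_hz = c(0.1, 6),
                       rest_gain_anterior = 2.5,
                       locomotion_suppression = 0.3,
                       bilateral_r = 0.9,
                       hrf = list(shape = 2.5, scale = 0.35, amplitude = 12),
                       hrf_lag_s = 1.5,
                       pupil_decay_tau_s = 15,
                       pupil_base_px = 30,
                       pupil_gain = 0.5,
                       artifact_heart_hz = 9,
                       artifact_breath_hz = 2.5,
                       artifact_heart_uM = 0.3,
                       artifact_breath_uM = 0.5,
                       dff_scale = 0.08,
                       pixel_noise_sd = 0.3,
                       channel_noise_sd = c(fluor = 0, green = 0, red = 0),
                       seed = 1L) {
  stopifnot_scalar_pos(frame_rate, "frame_rate")
  stopifnot_scalar_pos(duration_s, "duration_s")
  if (locomotion_suppression <= 0 || locomotion_suppression >= 1)
    stop("'locomotion_suppression' must be in (0, 1)", call. = FALSE)
  if (hrf_lag_s < 0) stop("'hrf_lag_s' must be >= 0", call. = FALSE)
  if (bilateral_r < 0 || bilateral_r > 1)
    stop("'bilateral_r' must be in [0, 1]", call. = FALSE)
  if (rest_band_hz[2] >= frame_rate / 2)
    stop("rest band must lie below the Nyquist frequency", call. = FALSE)
  cfg <- list(frame_rate = frame_rate, duration_s = duration_s,
              image_shape = as.integer(image_shape),
              n_parcels_per_hemisphere = as.integer(n_parcels_per_hemisphere),
              midline_gap = as.integer(midline_gap),
              bout_rate_per_min = bout_rate_per_min,
              bout_duration_range = bout_duration_range,
              rest_band_hz = rest_band_hz,
              rest_gain_anterior = rest_gain_anterior,
              locomotion_suppression = locomotion_suppression,
              bilateral_r = bilateral_r,
              hrf = hrf, hrf_lag_s = hrf_lag_s,
              pupil_decay_tau_s = pupil_decay_tau_s,
              pupil_base_px = pupil_base_px, pupil_gain = pupil_gain,
              artifact_heart_hz = artifact_heart_hz,
              artifact_breath_hz = artifact_breath_hz,
              artifact_heart_uM = artifact_heart_uM,
              artifact_breath_uM = artifact_breath_uM,
              dff_scale = dff_scale, pixel_noise_sd = pixel_noise_sd,
              channel_noise_sd = channel_noise_sd,
              seed = as.integer(seed))
  structure(cfg, class = "sim_config")
}

## Unit-variance, zero-mean band-limited process: an Ornstein-Uhlenbeck
## (AR(1)) stream band-passed in the FFT domain.
bandlimited_noise <- function(n, frame_rate, band, tau = 0.2) {
  x <- as.numeric(stats::filter(stats::rnorm(n), exp(-1 / (frame_rate * tau)),
                                method = "recursive"))
  X <- stats::fft(x)
  f <- (seq_len(n) - 1) * frame_rate / n
  f <- pmin(f, frame_rate - f)
  keep <- f >= band[1] & f <= band[2]
  x <- Re(stats::fft(X * keep, inverse = TRUE)) / n
  (x - mean(x)) / stats::sd(x)
}

## raised-cosine bumps (0..1) of width w_s centered per event frame
event_bumps <- function(event_frames, n, frame_rate, w_s = 4, center_offset_s = 1) {
  out <- numeric(n)
  w <- round(w_s * frame_rate)
  for (ev in event_frames) {
    start <- ev - round(center_offset_s * frame_rate)
    idx <- start:(start + w - 1L)
    ok <- idx >= 1L & idx <= n
    out[idx[ok]] <- out[idx[ok]] + sin(pi * (seq_len(w)[ok] - 0.5) / w)^2
  }
  pmin(out, 1)
}

#' Simulate behavior for a synthetic session
#'
#' Generates wheel velocity with rectangular-ish locomotion bouts (smoothed
#' edges and within-bout speed jitter), an arousal level that saturates
#' during locomotion and decays exponentially after locomotion offset (with
#' occasional re-arousal transients during prolonged rest), pupil diameter
#' tracking arousal -- hence rising with locomotion and decaying with time
#' constant `pupil_decay_tau_s` after offset -- and whisking elevated around
#' bouts.
#'
#' @param config a [sim_config()].
#' @return list with `behavior` (class `behavior_trace`: `wheel_velocity`,
#'   `pupil_diameter`, `whisk_speed`, `frame_rate`), `bouts` (ground-truth
#'   bout table: onset/offset frames, half-open `[onset, offset)`),
#'   `arousal` (per-frame level in \[0, 1\]) and `threshold` (the velocity
#'   threshold defining the truth bouts).
#' @export
simulate_behavior <- function(config) {
  set.seed(config$seed)
  fr <- config$frame_rate
  n <- round(config$duration_s * fr)
  dt <- 1 / fr
  v <- numeric(n)
  onsets_s <- c(); durs_s <- c()
  if (config$bout_rate_per_min > 0) {
    mean_dur <- mean(config$bout_duration_range)
    mean_gap <- max(20, 60 / config$bout_rate_per_min - mean_dur)
    t <- max(65, stats::runif(1, 0.8, 1.2) * mean_gap)
    repeat {
      dur <- stats::runif(1, config$bout_duration_range[1], config$bout_duration_range[2])
      if (t + dur + 10 > config$duration_s) break
      onsets_s <- c(onsets_s, t); durs_s <- c(durs_s, dur)
      t <- t + dur + stats::runif(1, 0.7, 1.3) * mean_gap
    }
    if (!length(onsets_s))
      warning("duration too short to contain a locomotion bout at the requested rate")
    for (b in seq_along(onsets_s)) {
      i0 <- round(onsets_s[b] * fr) + 1L
      nb <- round(durs_s[b] * fr)
      amp <- stats::runif(1, 4, 8)
      ramp <- round(0.5 * fr)
      env <- rep(1, nb)
      env[seq_len(ramp)] <- sin(pi * seq_len(ramp) / (2 * ramp))^2
      env[nb + 1L - seq_len(ramp)] <- env[seq_len(ramp)]
      jit <- stats::filter(stats::rnorm(nb, 0, 0.15), rep(1 / 5, 5), sides = 2)
      jit[is.na(jit)] <- 0
      idx <- i0:(i0 + nb - 1L)
      v[idx] <- pmax(0, amp * env * (1 + as.numeric(jit)))
    }
  }
  threshold <- if (any(v > 0)) 0.05 * stats::quantile(v, 0.99, names = FALSE) else 0
  ## ground-truth bouts: supra-threshold runs of the generated velocity
  bouts <- runs_to_bouts(v > threshold, fr)
  ## arousal: saturates in bouts (tau 2 s), exponential decay after offset
  in_bout <- v > threshold
  A <- numeric(n)
  a <- 0
  decay <- exp(-dt / config$pupil_decay_tau_s)
  for (i in seq_len(n)) {
    a <- if (in_bout[i]) a + dt * (1 - a) / 2 else a * decay
    A[i] <- a
  }
  ## slow arousal wander during prolonged rest: after the initial decay has
  ## run its course the mouse drifts in and out of higher and lower arousal;
  ## gated in only past the sustained-rest sampling point (55-70 s after
  ## offset) so the stereotyped initial -> sustained transition stays clean
  if (nrow(bouts) && any(!in_bout)) {
    since_off <- rep(Inf, n)
    last_off <- NA_integer_
    for (i in seq_len(n)) {
      if (in_bout[i]) last_off <- i + 1L
      else if (!is.na(last_off)) since_off[i] <- (i - last_off) * dt
    }
    gate <- pmin(1, pmax(0, (since_off - 55) / 15))
    gate[in_bout] <- 0
    wander <- 0.85 * stats::pnorm(1.2 * bandlimited_noise(n, fr, c(0.01, 0.08), tau = 5))
    A <- pmin(1, A + gate * wander)
  }
  pupil <- config$pupil_base_px * (1 + config$pupil_gain * A)
  whisk_noise <- abs(stats::filter(stats::rnorm(n, 0, 0.2), rep(1 / 3, 3), sides = 2))
  whisk_noise[is.na(whisk_noise)] <- 0
  pre <- if (nrow(bouts)) event_bumps(bouts$onset, n, fr, w_s = 3, center_offset_s = 1.5)
         else numeric(n)
  whisk <- 0.2 + 1.2 * A + 0.8 * pre + as.numeric(whisk_noise)
  behavior <- structure(list(wheel_velocity = v, pupil_diameter = pupil,
                             whisk_speed = whisk, frame_rate = fr),
                        class = "behavior_trace")
  list(behavior = behavior, bouts = bouts, arousal = A, threshold = threshold)
}

## logical run-length encoding of supra-threshold locomotion into a bout table
runs_to_bouts <- function(active, frame_rate) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  bouts <- data.frame(onset = starts[on], offset = ends[on] + 1L)
  bouts$duration_s <- (bouts$offset - bouts$onset) / frame_rate
  n <- length(active)
  bouts$pre_rest_s <- (bouts$onset - c(1L, bouts$offset[-nrow(bouts)])) / frame_rate
  bouts$post_rest_s <- (c(bouts$onset[-1L], n + 1L) - bouts$offset) / frame_rate
  bouts
}

## parcel geometry: rectangular tiles per hemisphere with a midline gap;
## roles by tile row (anterior / sensory / posterior quartiles)
parcel_geometry <- function(config) {
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  k <- config$n_parcels_per_hemisphere
  hemi <- hemisphere_columns(nc, config$midline_gap)
  divs <- which(k %% seq_len(k) == 0)
  tr <- min(divs[divs >= sqrt(k)])      # tile rows (prefer tall grids)
  tc <- k / tr
  row_band <- cut(seq_len(nr), tr, labels = FALSE)
  col_band_l <- cut(seq_along(hemi$left), tc, labels = FALSE)
  labels <- matrix(0L, nr, nc)
  tile_id <- function(rb, cb) (rb - 1L) * tc + cb
  for (i in seq_len(nr)) {
    labels[i, hemi$left] <- tile_id(row_band[i], col_band_l)
    labels[i, rev(hemi$right)] <- k + tile_id(row_band[i], col_band_l)
  }
  n_ant <- max(1L, ceiling(tr / 3))       # frontal third of the cortex
  n_post <- max(1L, floor(tr / 4))
  roles_row <- rep("sensory", tr)
  roles_row[seq_len(n_ant)] <- "anterior"
  roles_row[tr + 1L - seq_len(n_post)] <- "posterior"
  roles <- rep(roles_row, each = tc)      # per left-parcel id 1..k
  list(labels = labels, roles = roles,
       pairs = cbind(left = seq_len(k), right = k + seq_len(k)))
}

#' Simulate cortical dynamics with ground truth
#'
#' Builds parcel-structured pixel dynamics on a bilateral tiled geometry:
#' each bilateral parcel pair shares a band-limited latent fluctuation
#' (target correlation `bilateral_r`), anterior parcels carry high-gain
#' resting fluctuations that locomotion suppresses by
#' `locomotion_suppression` and whose amplitude and long-range coupling
#' depend on the arousal level (so that initial and sustained rest express
#' distinct correlation states), sensory parcels carry locomotion-locked
#' activation, and stereotyped cortex-wide co-activation patterns mark
#' locomotion onset and offset. Hemodynamics are the gamma-HRF convolution
#' of the neural drive, delayed by `hrf_lag_s`, with spatially uniform
#' cardiac and respiratory oscillations added; oxy-/deoxy-hemoglobin are
#' anti-correlated with `true_hbt = true_hbo + true_hbr` by construction.
#' The first 5 s form the baseline window: hemodynamics are clamped to zero
#' and F/F(base) to 1 there, ramping in over the following 2 s.
#'
#' @param config a [sim_config()].
#' @param beh result of [simulate_behavior()] for the same config.
#' @return object of class `ground_truth`: `parcel_labels`,
#'   `bilateral_pairs`, `roles`, `state_windows` (ground-truth state window
#'   table), `state_schedule` (per-frame factor; transition windows take
#'   precedence where windows overlap),
#'   `true_F` (pixel x time, F/F_base), `true_hbo`, `true_hbr`, `true_hbt`
#'   (uM), `parcel_signal` (parcel x time latent drive), `arousal`.
#' @export
simulate_cortex <- function(config, beh) {
  fr <- config$frame_rate
  n <- length(beh$behavior$wheel_velocity)
  if (n != round(config$duration_s * fr))
    stop("behavior length does not match the configured duration", call. = FALSE)
  set.seed(config$seed + 1L)
  dt <- 1 / fr
  geo <- parcel_geometry(config)
  k <- config$n_parcels_per_hemisphere
  v <- beh$behavior$wheel_velocity
  A <- beh$arousal
  in_bout <- v > beh$threshold
  smooth_ind <- stats::filter(as.numeric(in_bout), rep(1 / round(0.5 * fr), round(0.5 * fr)),
                              sides = 2)
  smooth_ind[is.na(smooth_ind)] <- 0
  smooth_ind <- as.numeric(smooth_ind)
  L <- v / max(stats::quantile(v, 0.99, names = FALSE), 1e-12)
  band <- config$rest_band_hz
  g <- bandlimited_noise(n, fr, band)               # shared long-range component
  ## stereotyped transition co-activations live on the locomotion side of
  ## each transition (anticipatory before onset, end-of-run before offset)
  ## so the initial-rest window stays a pure high-arousal rest signature
  bumps_on <- if (nrow(beh$bouts))
    event_bumps(beh$bouts$onset, n, fr, w_s = 4, center_offset_s = 4) else numeric(n)
  bumps_off <- if (nrow(beh$bouts))
    event_bumps(beh$bouts$offset, n, fr, w_s = 4, center_offset_s = 4) else numeric(n)
  ## per-pair transition-pattern weights (bilaterally symmetric, mixed signs)
  w_on <- sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 0.8, 1.6)
  w_off <- sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 0.8, 1.6)
  u_s <- stats::runif(k, -0.3, 0.3)                 # sensory activation variation
  env_ant <- ifelse(in_bout, config$rest_gain_anterior * config$locomotion_suppression,
                    config$rest_gain_anterior * (1 - 0.5 * A))
  ## arousal-dependent long-range coupling, a property of aroused rest:
  ## during locomotion the anterior territory is instead dominated by
  ## movement-related desynchronization
  c_ant <- (0.1 + 1.2 * A) * (1 - smooth_ind)
  ## shared gait-locked fluctuation marking locomotion windows
  gait <- bandlimited_noise(n, fr, c(1, 6)) * smooth_ind
  ## anterior network component of low-arousal (sustained) rest
  g_ant <- bandlimited_noise(n, fr, band)
  c_low <- 0.9 * (1 - A) * (1 - smooth_ind)
  sig <- matrix(0, 2L * k, n)                       # parcel x time latent drive
  br <- config$bilateral_r
  for (p in seq_len(k)) {
    z <- bandlimited_noise(n, fr, band)
    e <- bandlimited_noise(n, fr, band)
    xl <- z
    xr <- br * z + sqrt(1 - br^2) * e
    role <- geo$roles[p]
    trans <- 3 * (w_on[p] * bumps_on + w_off[p] * bumps_off)
    if (role == "anterior") {
      dl <- bandlimited_noise(n, fr, band)
      dr <- bandlimited_noise(n, fr, band)
      common <- c_ant * g + c_low * g_ant + 0.3 * L + trans
      sig[p, ] <- env_ant * xl + smooth_ind * dl + common
      sig[k + p, ] <- env_ant * xr + smooth_ind * dr + common
    } else if (role == "sensory") {
      common <- 0.8 * g + 1.5 * L * (1 + u_s[p]) + 1.2 * gait * (1 + u_s[p]) + trans
      sig[p, ] <- xl + common
      sig[k + p, ] <- xr + common
    } else {                                        # posterior
      common <- 0.8 * g + 0.2 * L + trans
      sig[p, ] <- xl + common
      sig[k + p, ] <- xr + common
    }
  }
  ## baseline clamp: zero dynamics in the first 5 s, cosine ramp over 2 s
  t_s <- (seq_len(n) - 1) * dt
  ramp <- ifelse(t_s < 5, 0, ifelse(t_s < 7, sin(pi * (t_s - 5) / 4)^2, 1))
  sig <- sweep(sig, 2L, ramp, "*")
  ## hemodynamics: gamma HRF convolution of the parcel drive, lagged
  kern_t <- seq(0, 8, by = dt)
  kern <- stats::dgamma(kern_t, shape = config$hrf$shape, scale = config$hrf$scale)
  kern <- kern / sum(kern)
  lagf <- round(config$hrf_lag_s * fr)
  hbt_par <- matrix(0, 2L * k, n)
  for (p in seq_len(2L * k)) {
    cv <- stats::convolve(sig[p, ], rev(kern), type = "open")[seq_len(n)]
    hbt_par[p, ] <- config$hrf$amplitude *
      c(rep(0, lagf), cv)[seq_len(n)]
  }
  hbt_par <- sweep(hbt_par, 2L, ramp, "*")
  heart <- config$artifact_heart_uM * sin(2 * pi * config$artifact_heart_hz * t_s +
                                            stats::runif(1, 0, 2 * pi)) * ramp
  breath <- config$artifact_breath_uM * sin(2 * pi * config$artifact_breath_hz * t_s +
                                              stats::runif(1, 0, 2 * pi)) * ramp
  ## broadcast to pixels
  lab_vec <- as.integer(geo$labels)
  npix <- length(lab_vec)
  pixrow <- ifelse(lab_vec > 0L, lab_vec, NA_integer_)
  sig_px <- matrix(0, npix, n)
  inmask <- !is.na(pixrow)
  sig_px[inmask, ] <- sig[pixrow[inmask], ]
  noise <- matrix(stats::rnorm(npix * n, 0, config$pixel_noise_sd), npix, n)
  noise <- sweep(noise, 2L, ramp, "*")
  true_F <- 1 + config$dff_scale * (sig_px + noise)
  rm(sig_px, noise)
  hbt_core <- matrix(0, npix, n)
  hbt_core[inmask, ] <- hbt_par[pixrow[inmask], ]
  osc_o <- 0.6 * breath + heart
  osc_r <- 0.4 * breath
  true_hbo <- sweep(1.35 * hbt_core, 2L, osc_o, "+")
  true_hbr <- sweep(-0.35 * hbt_core, 2L, osc_r, "+")
  rm(hbt_core)
  sched <- schedule_from_bouts(beh$bouts, fr, n)
  structure(list(parcel_labels = geo$labels, bilateral_pairs = geo$pairs,
                 roles = geo$roles, state_schedule = sched$schedule,
                 state_windows = sched$windows,
                 true_F = true_F, true_hbo = true_hbo, true_hbr = true_hbr,
                 true_hbt = true_hbo + true_hbr,
                 parcel_signal = sig, parcel_hbt = hbt_par,
                 arousal = A, baseline_frames = which(t_s < 5)),
            class = "ground_truth")
}

## ground-truth state windows and per-frame schedule from the bout table,
## by direct arithmetic on the behavioral state definitions (kept separate
## from the window-extraction code in the states module; their agreement is
## tested). In the schedule, transition windows (onset/offset) take
## precedence over the rest-state windows they partially overlap.
schedule_from_bouts <- function(bouts, frame_rate, n) {
  w <- round(10 * frame_rate)
  h <- w %/% 2L
  rows <- list()
  add <- function(state, start, b) {
    if (start >= 1L && start + w - 1L <= n)
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
  win <- if (length(rows)) do.call(rbind, rows)
         else data.frame(state = character(), start = integer(),
                         end = integer(), bout_id = integer())
  win$state <- factor(win$state, levels = state_names())
  lab <- rep("other", n)
  for (s in c("sustained_rest", "initial_rest", "locomotion", "offset", "onset")) {
    for (i in which(win$state == s)) lab[win$start[i]:(win$end[i] - 1L)] <- s
  }
  list(windows = win,
       schedule = factor(lab, levels = c(state_names(), "other")))
}

#' Render raw optical channels from ground truth
#'
#' Forward Beer-Lambert model: the reflectance channels attenuate the
#' incident intensity by `exp(-d_mu_a(lambda) * X_R(lambda))` where the
#' absorption change `d_mu_a` follows from the simulated hemoglobin
#' concentrations; the raw fluorescence is the baseline intensity times
#' `F/F_base` times the excitation- and emission-side attenuations, whose
#' exponents are the reflectance exponents scaled by the pathlength ratios
#' `Pg` and `Pr`. Inverting this model with [convert_hemoglobin()] and
#' [correct_fluorescence()] recovers the truth exactly.
#'
#' @param truth a `ground_truth` from [simulate_cortex()].
#' @param optics an [optical_model()] (its `Pg`, `Pr` become the session's
#'   true ratios).
#' @param config the [sim_config()] used.
#' @param beh the [simulate_behavior()] result (behavior is attached to the
#'   session).
#' @return object of class `raw_session`: `fluor_raw`, `green_raw`,
#'   `red_raw` (pixel x time), `frame_rate`, `behavior`, `baseline_window`,
#'   `image_shape`, `true_Pg`, `true_Pr`.
#' @export
render_raw <- function(truth, optics, config, beh) {
  npix <- nrow(truth$true_F)
  n <- ncol(truth$true_F)
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  ## smooth illumination gradient (uneven illumination cancels on division)
  rows <- (seq_len(nr) - 1) / max(nr - 1, 1)
  cols <- (seq_len(nc) - 1) / max(nc - 1, 1)
  illum <- 1 + 0.2 * outer(rows, cols, function(a, b) a * 0.5 + b * 0.5)
  illum <- as.vector(illum)
  eg <- optics$epsilon["green", ]; er <- optics$epsilon["red", ]
  dmua_g <- eg[["hbo"]] * truth$true_hbo + eg[["hbr"]] * truth$true_hbr
  dmua_r <- er[["hbo"]] * truth$true_hbo + er[["hbr"]] * truth$true_hbr
  exps <- -dmua_g * optics$X_R[["green"]]
  expr_ <- -dmua_r * optics$X_R[["red"]]
  bad <- which(!is.finite(exps) | !is.finite(expr_))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(exps))
    stop(sprintf("non-finite optical exponent at pixel %d, frame %d", ij[1], ij[2]),
         call. = FALSE)
  }
  green_att <- exp(exps)
  red_att <- exp(expr_)
  green_raw <- (1000 * illum) * green_att
  red_raw <- (800 * illum) * red_att
  fluor_raw <- (500 * illum) * truth$true_F * green_att^optics$Pg * red_att^optics$Pr
  ns <- config$channel_noise_sd
  if (any(ns > 0)) {
    mul <- function(m, s) if (s > 0) m * exp(stats::rnorm(length(m), 0, s)) else m
    set.seed(config$seed + 2L)
    fluor_raw <- mul(fluor_raw, ns[["fluor"]])
    green_raw <- mul(green_raw, ns[["green"]])
    red_raw <- mul(red_raw, ns[["red"]])
  }
  structure(list(fluor_raw = fluor_raw, green_raw = green_raw, red_raw = red_raw,
                 frame_rate = config$frame_rate, behavior = beh$behavior,
                 baseline_window = c(1L, 100L),
                 image_shape = config$image_shape,
                 true_Pg = optics$Pg, true_Pr = optics$Pr),
            class = "raw_session")
}

#' Simulate a complete synthetic session
#'
#' Runs [simulate_behavior()], [simulate_cortex()] and [render_raw()] under
#' one seed and returns all pieces.
#'
#' @param config a [sim_config()].
#' @param optics an [optical_model()] (default [default_optics()]).
#' @return list with `config`, `optics`, `behavior`, `bouts`, `arousal`,
#'   `threshold`, `truth`, `raw`.
#' @export
simulate_session <- function(config = sim_config(), optics = default_optics()) {
  beh <- simulate_behavior(config)
  truth <- simulate_cortex(config, beh)
  raw <- render_raw(truth, optics, config, beh)
  list(config = config, optics = optics, behavior = beh$behavior,
       bouts = beh$bouts, arousal = beh$arousal, threshold = beh$threshold,
       truth = truth, raw = raw)
}

#' Export a behavior trace as CSV
#'
#' Columns: frame, wheel_velocity, pupil_diameter, whisk_speed.
#'
#' @param behavior a `behavior_trace`.
#' @param path output path.
#' @export
write_behavior_csv <- function(behavior, path) {
  utils::write.csv(data.frame(frame = seq_along(behavior$wheel_velocity),
                              wheel_velocity = behavior$wheel_velocity,
                              pupil_diameter = behavior$pupil_diameter,
                              whisk_speed = behavior$whisk_speed),
                   path, row.names = FALSE)
  invisible(path)
}
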