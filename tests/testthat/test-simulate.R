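test_that("sessions are bit-identical under a fixed seed", {
  cfg <- sim_config(duration_s = 60, image_shape = c(10, 12), seed = 42)
  s1 <- suppressWarnings(simulate_session(cfg))
  s2 <- suppressWarnings(simulate_session(cfg))
  expect_identical(s1$behavior, s2$behavior)
  expect_identical(s1$truth$true_F, s2$truth$true_F)
  expect_identical(s1$raw$fluor_raw, s2$raw$fluor_raw)
})

test_that("degenerate behavior configurations are handled", {
  cfg0 <- sim_config(duration_s = 120, bout_rate_per_min = 0, seed = 1)
  beh <- simulate_behavior(cfg0)
  expect_true(all(beh$behavior$wheel_velocity == 0))
  expect_true(all(beh$behavior$pupil_diameter == cfg0$pupil_base_px))
  expect_equal(nrow(beh$bouts), 0)

  cfg_short <- sim_config(duration_s = 30, seed = 1)
  expect_warning(b2 <- simulate_behavior(cfg_short), "too short")
  expect_equal(nrow(b2$bouts), 0)
})

test_that("post-offset pupil decay recovers the configured time constant", {
  cfg <- sim_config(duration_s = 3600, image_shape = c(10, 12), seed = 9)
  beh <- simulate_behavior(cfg)
  fr <- cfg$frame_rate
  b <- beh$bouts[beh$bouts$post_rest_s >= 50, ]
  expect_gte(nrow(b), 20)
  span <- round(45 * fr)
  traces <- vapply(b$offset, function(off)
    beh$behavior$pupil_diameter[off:(off + span - 1)], numeric(span))
  avg <- rowMeans(traces)
  t_s <- (seq_len(span) - 1) / fr
  # scaleOffset keeps the convergence test meaningful for a near-exact fit
  fit <- nls(avg ~ p0 + a * exp(-t_s / tau),
             start = list(p0 = cfg$pupil_base_px, a = 10, tau = 10),
             control = nls.control(maxiter = 200, scaleOffset = 1))
  tau_hat <- coef(fit)[["tau"]]
  expect_lt(abs(tau_hat - cfg$pupil_decay_tau_s) / cfg$pupil_decay_tau_s, 0.1)
})

test_that("cortical dynamics express the configured state structure", {
  ses <- state_session()
  cfg <- ses$config
  sched <- as.character(ses$truth$state_schedule)
  ant <- which(ses$truth$roles == "anterior")[1]
  sig <- ses$truth$parcel_signal

  # anterior variance: sustained rest vs mid-locomotion ratio > 2
  v_rest <- var(sig[ant, sched == "sustained_rest"])
  v_loco <- var(sig[ant, sched == "locomotion"])
  expect_gt(v_rest / v_loco, 2)

  # bilateral correlation of paired anterior parcels during rest
  k <- cfg$n_parcels_per_hemisphere
  rest_frames <- which(ses$behavior$wheel_velocity <= ses$threshold)
  rest_frames <- rest_frames[rest_frames > 7 * cfg$frame_rate]  # past baseline clamp
  r_bi <- cor(sig[ant, rest_frames], sig[ant + k, rest_frames])
  expect_gte(r_bi, 0.8)
  expect_lte(r_bi, 0.97)

  # ground-truth hemoglobin identity
  expect_equal(ses$truth$true_hbt, ses$truth$true_hbo + ses$truth$true_hbr)

  # neurovascular coupling: hbt lags the drive by hrf_lag + gamma mode
  hbt <- ses$truth$parcel_hbt[ant, ]
  cc <- ccf(hbt, sig[ant, ], lag.max = 100, plot = FALSE)
  peak_lag_s <- cc$lag[which.max(cc$acf)] / cfg$frame_rate
  mode_s <- (cfg$hrf$shape - 1) * cfg$hrf$scale
  expect_lt(abs(peak_lag_s - (cfg$hrf_lag_s + mode_s)), 0.25)
})

test_that("anterior resting fluctuations concentrate in the configured band", {
  ses <- state_session()
  cfg <- ses$config
  parc <- parcellation_map(ses$truth$parcel_labels, ses$truth$bilateral_pairs)
  roi <- extract_roi_timecourses(ses$truth$true_F, parc, cfg$frame_rate)
  ant <- which(ses$truth$roles == "anterior")[1]
  epochs <- detect_rest_epochs(ses$behavior$wheel_velocity, cfg$frame_rate,
                               threshold = ses$threshold)
  e <- epochs[which.max(epochs$duration_s), ]
  x <- roi$values[ant, e$start:(e$end - 1)]
  psd <- welch_psd(x - mean(x), cfg$frame_rate, seg_s = 20)
  inband <- psd$freq >= cfg$rest_band_hz[1] & psd$freq <= cfg$rest_band_hz[2]
  all10 <- psd$freq <= 10
  expect_gte(sum(psd$power[inband]) / sum(psd$power[all10]), 0.8)
})

test_that("rendering obeys the no-absorption limit and flags bad exponents", {
  cfg <- sim_config(duration_s = 30, image_shape = c(8, 10), seed = 2,
                    bout_rate_per_min = 0)
  beh <- simulate_behavior(cfg)
  truth <- simulate_cortex(cfg, beh)
  truth$true_hbo[] <- 0; truth$true_hbr[] <- 0
  optics <- default_optics()
  raw <- render_raw(truth, optics, cfg, beh)
  # constant reflectance; fluorescence / baseline = true_F exactly
  expect_equal(max(apply(raw$green_raw, 1, sd)), 0)
  expect_equal(max(apply(raw$red_raw, 1, sd)), 0)
  base <- raw$fluor_raw[, 1] / truth$true_F[, 1]
  expect_equal(raw$fluor_raw / base, truth$true_F, tolerance = 1e-12)

  truth$true_hbo[3, 7] <- Inf
  expect_error(render_raw(truth, optics, cfg, beh), "pixel 3, frame 7")
})

test_that("behavior exports round-trip through CSV", {
  ses <- small_session()
  f <- tempfile(fileext = ".csv")
  write_behavior_csv(ses$behavior, f)
  d <- read.csv(f)
  expect_equal(d$wheel_velocity, ses$behavior$wheel_velocity)
  expect_equal(d$pupil_diameter, ses$behavior$pupil_diameter)
  unlink(f)
})

test_that("optics constants round-trip through YAML", {
  o <- default_optics(Pg = 0.3, Pr = 1.2)
  f <- tempfile(fileext = ".yaml")
  write_optics_yaml(o, f)
  o2 <- read_optics_yaml(f)
  expect_equal(o2$epsilon, o$epsilon, tolerance = 1e-8)
  expect_equal(o2$Pg, 0.3)
  expect_equal(o2$Pr, 1.2)
  unlink(f)
})
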