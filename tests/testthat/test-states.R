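test_that("bout detection finds planted runs and merges close ones", {
  fr <- 20
  expect_equal(nrow(detect_bouts(rep(0, 2000), fr, threshold = 1)), 0)

  v <- rep(0, 3000); v[1000:1399] <- 5
  b <- detect_bouts(v, fr, threshold = 1)
  expect_equal(nrow(b), 1)
  expect_equal(b$onset, 1000)
  expect_equal(b$offset, 1400)
  expect_equal(b$duration_s, 20)
  expect_equal(b$pre_rest_s, 999 / fr)

  # two runs separated by half the merge gap become one bout
  v2 <- rep(0, 3000); v2[1000:1199] <- 5; v2[1210:1399] <- 5
  b2 <- detect_bouts(v2, fr, threshold = 1, min_gap_s = 1)
  expect_equal(nrow(b2), 1)
  expect_equal(c(b2$onset, b2$offset), c(1000, 1400))
})

test_that("state windows follow the behavioral definitions", {
  fr <- 20
  n <- 20000
  mkbouts <- function(on_s, dur_s) {
    v <- rep(0, n)
    for (i in seq_along(on_s)) {
      v[(on_s[i] * fr + 1):((on_s[i] + dur_s[i]) * fr)] <- 5
    }
    detect_bouts(v, fr, threshold = 1)
  }
  # 15-s bout with 70-s rest on both sides: onset, initial and sustained rest,
  # but no locomotion/offset windows (duration < 20 s)
  b <- mkbouts(70, 15)
  w <- extract_state_windows(b, fr, n)
  expect_setequal(as.character(w$state), c("onset", "initial_rest", "sustained_rest"))
  on <- b$onset; off <- b$offset
  expect_equal(w$start[w$state == "onset"], on - 100)
  expect_equal(w$start[w$state == "initial_rest"], off)
  expect_equal(w$start[w$state == "sustained_rest"], off + 800)

  # 8-s bout: no onset window
  w8 <- extract_state_windows(mkbouts(70, 8), fr, n)
  expect_false("onset" %in% w8$state)

  # 30-s bout: locomotion window is the central 10 s
  b30 <- mkbouts(70, 30)
  w30 <- extract_state_windows(b30, fr, n)
  loc <- w30[w30$state == "locomotion", ]
  expect_equal(loc$start, b30$onset + 10 * fr)
  expect_equal(loc$end, b30$onset + 20 * fr)

  # invariance to trailing/leading rest padding
  v <- rep(0, n); v[(70 * fr + 1):(100 * fr)] <- 5
  b1 <- detect_bouts(v, fr, threshold = 1)
  b2 <- detect_bouts(c(v, rep(0, 4000)), fr, threshold = 1)
  w1 <- extract_state_windows(b1, fr, n)
  w2 <- extract_state_windows(b2, fr, n + 4000)
  expect_equal(w1[c("state", "start", "end")], w2[c("state", "start", "end")])
})

test_that("generator state windows agree with extracted state windows", {
  ses <- state_session()
  fr <- ses$config$frame_rate
  n <- length(ses$behavior$wheel_velocity)
  bouts <- detect_bouts(ses$behavior$wheel_velocity, fr,
                        threshold = ses$threshold)
  wins <- extract_state_windows(bouts, fr, n)
  truth_wins <- ses$truth$state_windows
  ord <- function(w) w[order(w$state, w$start), c("state", "start", "end")]
  expect_equal(ord(wins), ord(truth_wins), ignore_attr = TRUE)

  # every frame the schedule labels belongs to a window of a state that
  # covers it (transitions take precedence where windows overlap)
  sched <- as.character(ses$truth$state_schedule)
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(wins))) covered[wins$start[i]:(wins$end[i] - 1)] <- TRUE
  expect_true(all(sched[!covered] == "other"))
  for (i in seq_len(nrow(wins))) {
    frames <- wins$start[i]:(wins$end[i] - 1)
    expect_true(all(sched[frames] != "other"))
  }
})

test_that("state basis averaging matches the arithmetic mean oracle", {
  set.seed(41)
  fr <- 20
  roi <- roi_matrix(matrix(rnorm(4 * 4000), 4), fr, "raw")
  cs <- windowed_correlation(roi, 10, 1)
  wins <- data.frame(state = factor(state_names(), levels = state_names()),
                     start = c(1, 401, 801, 1201, 1601),
                     end = c(201, 601, 1001, 1401, 1801),
                     bout_id = 1:5)
  basis <- build_state_basis(cs, wins)
  expect_equal(basis$maps[, , "offset"], cs$maps[, , 801], tolerance = 1e-12)

  # duplicated windows leave the mean unchanged
  basis2 <- build_state_basis(cs, rbind(wins, wins))
  expect_equal(basis2$maps, basis$maps, tolerance = 1e-12)

  # 3-window mean equals the elementwise mean
  wins3 <- rbind(wins, transform(wins[wins$state == "onset", ], start = 2001, end = 2201),
                 transform(wins[wins$state == "onset", ], start = 2401, end = 2601))
  b3 <- build_state_basis(cs, wins3)
  expect_equal(b3$maps[, , "onset"],
               (cs$maps[, , 1] + cs$maps[, , 2001] + cs$maps[, , 2401]) / 3,
               tolerance = 1e-12)

  expect_error(build_state_basis(cs, wins[-2, ]), "locomotion")
})

test_that("NNLS state fits match the projected-gradient oracle", {
  set.seed(42)
  p <- 10
  nut <- p * (p - 1) / 2
  # synthetic independent basis of unit-diagonal symmetric maps
  mk <- function() {
    v <- tanh(rnorm(nut, sd = 0.5))
    corticostate:::vec_to_corr_map(v, p)
  }
  maps <- array(NA_real_, c(p, p, 5), dimnames = list(NULL, NULL, state_names()))
  for (s in 1:5) maps[, , s] <- mk()
  basis <- structure(list(maps = maps, n_windows = rep(1L, 5),
                          source_windows = NULL), class = "state_basis")
  X <- apply(maps, 3, corticostate:::upper_tri_vec)

  # series whose maps are exact members / exact mixtures of the basis
  target <- array(NA_real_, c(p, p, 3))
  target[, , 1] <- maps[, , 2]
  mix <- 0.3 * X[, 1] + 0.7 * X[, 4]
  target[, , 2] <- corticostate:::vec_to_corr_map(mix, p)
  target[, , 3] <- 0                      # all-zero map -> residual defined as 1
  cs <- structure(list(maps = target, starts = c(1, 2, 3), centers = c(1, 2, 3),
                       window_frames = 200L, window_s = 10, step_frames = 1L,
                       frame_rate = 20, signal_kind = "neural_dff"),
                  class = "corr_map_series")
  fit <- fit_states_nnls(cs, basis = basis, cv_folds = 1)
  expect_true(all(fit$coefficients >= 0))
  expect_equal(fit$coefficients[, 1], c(onset = 0, locomotion = 1, offset = 0,
                                        initial_rest = 0, sustained_rest = 0),
               tolerance = 1e-8)
  expect_lt(fit$residual[1], 1e-10)
  expect_equal(unname(fit$coefficients[, 2]), c(0.3, 0, 0, 0.7, 0), tolerance = 1e-6)
  oracle <- proj_grad_nnls(X, mix)
  expect_equal(unname(fit$coefficients[, 2]), oracle, tolerance = 1e-6)
  expect_equal(fit$residual[3], 1)
  expect_equal(unname(fit$coefficients[, 3]), rep(0, 5))
})

test_that("state_fit methods expose coefficients, predictions and residuals", {
  ses <- state_session()
  fr <- ses$config$frame_rate
  roi <- truth_roi(ses)
  cs <- windowed_correlation(roi, 10, 1)
  bouts <- detect_bouts(ses$behavior$wheel_velocity, fr)
  wins <- extract_state_windows(bouts, fr, ncol(roi$values))
  fit <- suppressWarnings(fit_states_nnls(cs, windows = wins, cv_folds = 2, seed = 1))

  expect_s3_class(fit, "state_fit")
  expect_identical(dim(coef(fit)), c(5L, dim(cs$maps)[3]))
  expect_true(all(coef(fit) >= 0))
  expect_length(residuals(fit), dim(cs$maps)[3])
  expect_true(all(residuals(fit) >= 0))

  pr <- predict(fit, windows = 1:3)
  X <- apply(fit$basis$maps, 3, corticostate:::upper_tri_vec)
  expect_equal(pr, X %*% coef(fit)[, 1:3], tolerance = 1e-12)
  prm <- predict(fit, windows = 1:2, as_maps = TRUE)
  expect_equal(dim(prm), c(16, 16, 2))
  expect_equal(diag(prm[, , 1]), rep(1, 16))

  s <- summary(fit)
  expect_s3_class(s, "summary.state_fit")
  expect_output(print(fit), "cross-validated")
  expect_output(print(s), "Residual quantiles")

  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("event-aligned coefficient averages match the arithmetic oracle", {
  co <- matrix(runif(5 * 500), 5, dimnames = list(state_names(), NULL))
  fit <- structure(list(coefficients = co, residual = numeric(500),
                        centers = 1:500 + 100, starts = 1:500,
                        window_frames = 200L, frame_rate = 20,
                        signal_kind = "neural_dff",
                        cv = list(folds = 0)), class = "state_fit")
  bouts <- data.frame(onset = c(200, 300, 400), offset = c(240, 350, 460))

  # single bout: mean equals the trace, SEM = 0
  al1 <- align_coefficients(fit, bouts[1, ], "onset", span_s = c(-1, 1))
  rel <- seq(-20, 20)
  idx <- (200 + rel) - 100
  expect_equal(al1$mean, co[, idx], ignore_attr = TRUE)
  expect_true(all(al1$sem == 0))
  # time 0 is the event frame
  expect_equal(al1$time_s[which(rel == 0)], 0)
  expect_equal(al1$mean[, which(rel == 0)], co[, 200 - 100], ignore_attr = TRUE)

  # 3 bouts: mean and SEM equal direct arithmetic
  al3 <- align_coefficients(fit, bouts, "offset", span_s = c(-1, 1))
  idx3 <- vapply(bouts$offset, function(e) (e + rel) - 100, numeric(length(rel)))
  for (s in 1:5) {
    vals <- cbind(co[s, idx3[, 1]], co[s, idx3[, 2]], co[s, idx3[, 3]])
    expect_equal(al3$mean[s, ], rowMeans(vals), tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(al3$sem[s, ], apply(vals, 1, sd) / sqrt(3), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("rest reciprocity reports exact correlations per epoch", {
  n <- 1500
  c4 <- runif(n)
  co <- matrix(0.1, 5, n, dimnames = list(state_names(), NULL))
  co["initial_rest", ] <- c4
  co["sustained_rest", 1:750] <- 1 - c4[1:750]
  co["sustained_rest", 751:1500] <- c4[751:1500]
  fit <- structure(list(coefficients = co, residual = numeric(n),
                        centers = 1:n, starts = 1:n, window_frames = 200L,
                        frame_rate = 20, signal_kind = "neural_dff",
                        cv = list(folds = 0)), class = "state_fit")
  epochs <- data.frame(start = c(1, 751), end = c(751, 1501),
                       duration_s = c(37.5, 37.5))
  r <- rest_reciprocity(fit, epochs)
  expect_equal(r, c(-1, 1))

  co["sustained_rest", 1:750] <- 5   # constant -> skipped with warning
  fit$coefficients <- co
  expect_warning(r2 <- rest_reciprocity(fit, epochs), "constant")
  expect_true(is.na(r2[1]) && r2[2] == 1)
})

test_that("arousal association distributions behave and KS handles ties", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(ks_two_sample(x, x)$statistic, 0)
})
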