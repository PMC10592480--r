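test_that("baseline selection uses the first qualifying rest run", {
  ses <- small_session()
  n <- ncol(ses$raw$fluor_raw)

  b <- select_baseline(ses$raw, wheel_velocity = rep(0, n))
  expect_equal(b$frames, c(1L, 100L))
  expect_equal(b$green, rowMeans(ses$raw$green_raw[, 1:100]))

  const <- ses$raw
  const$fluor_raw[] <- 7; const$green_raw[] <- 3; const$red_raw[] <- 5
  b2 <- select_baseline(const, wheel_velocity = rep(0, n))
  expect_true(all(b2$fluor == 7) && all(b2$green == 3) && all(b2$red == 5))

  expect_error(select_baseline(ses$raw, wheel_velocity = rep(10, n), threshold = 1),
               "relaxing")
})

test_that("Beer-Lambert inversion recovers planted hemoglobin exactly", {
  optics <- default_optics()
  # baseline state: unit reflectance everywhere -> zero concentration change
  one <- matrix(1, 4, 10)
  h0 <- convert_hemoglobin(one, one, optics)
  expect_equal(max(abs(h0$d_hbo)), 0)
  expect_equal(max(abs(h0$d_hbt)), 0)

  # forward-generate from dHbO = +2, dHbR = -1 uM and invert
  hbo <- matrix(2, 3, 50); hbr <- matrix(-1, 3, 50)
  att <- function(lam) exp(-(optics$epsilon[lam, "hbo"] * hbo +
                             optics$epsilon[lam, "hbr"] * hbr) * optics$X_R[lam])
  h <- convert_hemoglobin(att("green"), att("red"), optics)
  expect_lt(max(abs(h$d_hbo - 2)), 1e-9)
  expect_lt(max(abs(h$d_hbr + 1)), 1e-9)

  # round trip over a +-50 uM range
  set.seed(1)
  hbo <- matrix(runif(200, -50, 50), 4); hbr <- matrix(runif(200, -50, 50), 4)
  h <- convert_hemoglobin(att("green"), att("red"), optics)
  expect_lt(max(abs(h$d_hbo - hbo)), 1e-8)
  expect_identical(h$d_hbt, h$d_hbo + h$d_hbr)

  expect_error(convert_hemoglobin(matrix(-1, 1, 1), matrix(1, 1, 1), optics),
               "nonpositive")
})

test_that("fluorescence correction limits and scale consistency hold", {
  set.seed(2)
  f <- matrix(runif(60, 0.8, 1.2), 3)
  g <- matrix(runif(60, 0.9, 1.1), 3)
  r <- matrix(runif(60, 0.9, 1.1), 3)

  expect_equal(correct_fluorescence(f, g, r, 0, 0)$dff, f - 1)
  one <- matrix(1, 3, 20)
  expect_equal(correct_fluorescence(f, one, one, 0.3, 1.7)$dff, f - 1)

  # doubling the fluorescence doubles dff + 1
  d1 <- correct_fluorescence(f, g, r, 0.25, 1.4)$dff
  d2 <- correct_fluorescence(2 * f, g, r, 0.25, 1.4)$dff
  expect_equal(d2 + 1, 2 * (d1 + 1), tolerance = 1e-12)
  expect_error(correct_fluorescence(f, -g, r, 0.25, 1.4), "positive")
})

test_that("rendered sessions invert exactly through the spectroscopy chain", {
  ses <- small_session()
  nrm <- corticostate:::normalize_session(ses$raw)
  h <- convert_hemoglobin(nrm$green_norm, nrm$red_norm, ses$optics)
  expect_lt(max(abs(h$d_hbo - ses$truth$true_hbo)), 1e-9)
  expect_lt(max(abs(h$d_hbr - ses$truth$true_hbr)), 1e-9)

  fl <- correct_fluorescence(nrm$fluor_norm, nrm$green_norm, nrm$red_norm,
                             ses$raw$true_Pg, ses$raw$true_Pr)
  rel <- abs((fl$dff + 1) - ses$truth$true_F) / ses$truth$true_F
  expect_lt(max(rel), 1e-10)
})

test_that("correction removes absorption cross-talk from constant fluorescence", {
  # constant neural signal, strong hemodynamics
  optics <- default_optics()
  set.seed(3)
  npix <- 30; n <- 400
  hbt <- matrix(rep(sin(2 * pi * (1:n) / 80) * 10, each = npix), npix)
  hbo <- 1.3 * hbt; hbr <- -0.3 * hbt
  g <- exp(-(optics$epsilon["green", "hbo"] * hbo +
             optics$epsilon["green", "hbr"] * hbr) * optics$X_R["green"])
  r <- exp(-(optics$epsilon["red", "hbo"] * hbo +
             optics$epsilon["red", "hbr"] * hbr) * optics$X_R["red"])
  f_raw <- 1 * g^optics$Pg * r^optics$Pr          # F(t)/F(base) = 1
  corrected <- correct_fluorescence(f_raw, g, r, optics$Pg, optics$Pr)$dff
  uncorrected <- f_raw - 1
  expect_lt(stats::var(as.vector(corrected)),
            1e-6 * stats::var(as.vector(uncorrected)))
})

test_that("pathlength-ratio estimation recovers the rendering values", {
  # truth with fluorescence drive uncorrelated from the hemodynamic drive
  cfg <- sim_config(duration_s = 120, image_shape = c(10, 12), seed = 5,
                    pixel_noise_sd = 0)
  beh <- suppressWarnings(simulate_behavior(cfg))
  truth <- suppressWarnings(simulate_cortex(cfg, beh))
  set.seed(9)  # replace neural truth by noise uncorrelated with hemodynamics
  truth$true_F <- matrix(1, nrow(truth$true_F), ncol(truth$true_F)) +
    0.05 * matrix(rnorm(length(truth$true_F)), nrow(truth$true_F))
  optics <- default_optics(Pg = 0.25, Pr = 1.4)
  raw <- render_raw(truth, optics, cfg, beh)

  est <- estimate_pathlength_ratios(raw, optics,
                                    pg_grid = seq(0.05, 0.45, by = 0.05),
                                    pr_grid = seq(1.0, 1.8, by = 0.1))
  expect_lte(abs(est$Pg - 0.25), 0.05 + 1e-12)
  expect_lte(abs(est$Pr - 1.4), 0.1 + 1e-12)

  # objective at the truth beats the uncorrected corner on the same grid
  est2 <- estimate_pathlength_ratios(raw, optics, pg_grid = c(0, 0.25),
                                     pr_grid = c(0.5, 1.4))
  expect_lte(est2$objective["0.25", "1.4"], est2$objective["0", "0.5"])

  # degenerate session without hemodynamics errors out
  truth0 <- truth
  truth0$true_hbo[] <- 0; truth0$true_hbr[] <- 0
  raw0 <- render_raw(truth0, optics, cfg, beh)
  expect_error(estimate_pathlength_ratios(raw0, optics), "variation")
})
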