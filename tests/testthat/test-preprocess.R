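test_that("initial-volume discard shortens volume and confounds consistently", {
  v <- tiny_vol(nt = 240)
  cf <- confound_set(motion_fixture(240))
  out <- discard_initial_volumes(v, cf, 5)
  expect_equal(dim(out$vol$data)[4], 235)
  expect_equal(nrow(out$confounds$motion), 235)
  expect_equal(out$vol$data[, , , 1], v$data[, , , 6])

  id <- discard_initial_volumes(v, cf, 0)
  expect_equal(id$vol$data, v$data)
  expect_error(discard_initial_volumes(v, cf, 240), "discard")
})

test_that("framewise displacement follows the 50-mm scalar convention", {
  m <- motion_fixture(10)
  out <- compute_fd(m)
  expect_equal(out$fd, rep(0, 10))
  expect_equal(out$mean_fd, 0)

  # +0.1 mm translation step contributes exactly 0.1 mm at that frame
  m2 <- motion_fixture(10, step_at = 5, step = c(0.1, 0, 0, 0, 0, 0))
  fd2 <- compute_fd(m2)$fd
  expect_equal(fd2[5], 0.1)
  expect_equal(fd2[-5], rep(0, 9))

  # 0.002 rad rotation step contributes 50 * 0.002 = 0.1 mm
  m3 <- motion_fixture(10, step_at = 3, step = c(0, 0, 0, 0.002, 0, 0))
  expect_equal(compute_fd(m3)$fd[3], 0.1)

  expect_error(compute_fd(matrix(0, 10, 5)), "6 columns")
})

test_that("exclusion screen applies strict motion and performance rules", {
  rec <- list(hit_rate = 80)
  m_ok <- motion_fixture(10, step_at = 2, step = c(3.0, 0, 0, 0, 0, 0))
  expect_true(exclusion_screen(rec, m_ok)$keep)   # exactly 3.0 mm: keep

  m_bad <- motion_fixture(10, step_at = 2, step = c(3.1, 0, 0, 0, 0, 0))
  out <- exclusion_screen(rec, m_bad)
  expect_false(out$keep)
  expect_equal(out$reason, "motion")

  # rotation of 3.5 degrees
  m_rot <- motion_fixture(10, step_at = 2,
                          step = c(0, 0, 0, 3.5 * pi / 180, 0, 0))
  expect_equal(exclusion_screen(rec, m_rot)$reason, "motion")

  out2 <- exclusion_screen(list(hit_rate = 29), motion_fixture(10))
  expect_false(out2$keep)
  expect_equal(out2$reason, "performance")

  # missing hit rate: pass-through for rest, error for task screening
  expect_true(exclusion_screen(list(), motion_fixture(10))$keep)
  expect_error(exclusion_screen(list(), motion_fixture(10),
                                require_hit_rate = TRUE), "hit_rate")
})

test_that("scrubbing interpolates flagged volumes linearly", {
  # linear-in-time voxel series: interpolation is exact
  sdim <- c(4, 4, 4); nt <- 10
  base <- array(rep(seq_len(nt), each = prod(sdim)), c(sdim, nt))
  v <- vol4d(base, make_affine(3), 2.5)
  fd <- rep(0, nt); fd[5] <- 1
  out <- scrub_interpolate(v, fd, 0.5)
  expect_equal(out$data[, , , 5], base[, , , 5])

  # a run of 3 flagged points interpolates between the flanking frames
  fd3 <- rep(0, nt); fd3[4:6] <- 1
  v2 <- tiny_vol(sdim, nt)
  out2 <- scrub_interpolate(v2, fd3, 0.5)
  lo <- v2$data[, , , 3]; hi <- v2$data[, , , 7]
  expect_equal(out2$data[, , , 4], lo + (hi - lo) * 0.25)
  expect_equal(out2$data[, , , 5], lo + (hi - lo) * 0.5)
  expect_equal(out2$data[, , , 6], lo + (hi - lo) * 0.75)

  # no flags: identity; all flagged: error
  expect_equal(scrub_interpolate(v2, rep(0, nt), 0.5)$data, v2$data)
  expect_error(scrub_interpolate(v2, rep(1, nt), 0.5), "all timepoints")
})

test_that("spatial smoothing matches the closed-form Gaussian on a delta", {
  sdim <- c(15, 15, 15)
  dat <- array(0, c(sdim, 1)); dat[8, 8, 8, 1] <- 1
  v <- vol4d(dat, make_affine(3), 2.5)
  out <- spatial_smooth(v, fwhm = 8)
  sd_mm <- 8 / (2 * sqrt(2 * log(2)))
  ratio <- out$data[9, 8, 8, 1] / out$data[8, 8, 8, 1]
  expect_equal(ratio, exp(-3^2 / (2 * sd_mm^2)), tolerance = 0.01)
  # interior delta: total mass preserved within 0.1 %
  expect_equal(sum(out$data), 1, tolerance = 1e-3)
  # fwhm = 0 is the identity
  expect_equal(spatial_smooth(v, 0)$data, v$data)
})

test_that("band-pass filter keeps in-band and removes out-of-band sinusoids", {
  nt <- 235; tr <- 2.5
  tt <- (seq_len(nt) - 1) * tr
  mk <- function(f) {
    arr <- array(rep(sin(2 * pi * f * tt), each = 8), c(2, 2, 2, nt))
    vol4d(arr, make_affine(3), tr)
  }
  # frequencies on the Fourier grid near 0.04 and 0.15 Hz (an off-grid
  # sinusoid leaks across bins under any ideal filter)
  f_in <- round(0.04 * nt * tr) / (nt * tr)
  f_out <- round(0.15 * nt * tr) / (nt * tr)
  amp <- function(v) max(abs(v$data[1, 1, 1, ]))
  in_band <- temporal_bandpass(mk(f_in), 0.01, 0.08)
  expect_gt(amp(in_band), 0.95)
  expect_lt(amp(in_band), 1.05)
  out_band <- temporal_bandpass(mk(f_out), 0.01, 0.08)
  expect_lt(amp(out_band), 0.05)
  # off-grid in-band sinusoid keeps its power (RMS ratio near 1)
  ob <- temporal_bandpass(mk(0.04), 0.01, 0.08)
  expect_equal(sd(ob$data[1, 1, 1, ]) / sd(mk(0.04)$data[1, 1, 1, ]), 1,
               tolerance = 0.05)

  # constant series -> identically zero (DC removed)
  cv <- vol4d(array(7, c(2, 2, 2, nt)), make_affine(3), tr)
  expect_equal(max(abs(temporal_bandpass(cv, 0.01, 0.08)$data)), 0,
               tolerance = 1e-10)
  expect_error(temporal_bandpass(mk(0.04), 0.01, 0.3), "Nyquist")
})

test_that("task regressors are HRF-delayed non-negative boxcar responses", {
  d <- generate_task_design(n_blocks_per_session = 1, n_sessions = 1,
                            rng_seed = 2)
  sv <- session_n_vols(d, 2.5)
  reg <- build_task_regressors(d, 2.5, sv)
  expect_equal(colnames(reg), c("0-back", "1-back", "2-back"))
  # zero before the response can start, positive during the window,
  # bounded undershoot after it (the double-gamma kernel dips negative)
  w <- condition_windows(d, "2-back")
  mids <- (seq_len(sv) - 0.5) * 2.5
  expect_true(all(abs(reg[mids < w$onset[1] + 1, "2-back"]) < 1e-6))
  expect_true(all(reg[mids > w$onset[1] + 6 &
                        mids < w$onset[1] + w$duration[1], "2-back"] > 0))
  expect_gt(min(reg[, "2-back"]), -0.25 * max(reg[, "2-back"]))
  # convolution oracle: peak sits where the integrated positive HRF lobe
  # saturates, a few seconds past the first zero crossing of the kernel
  t_peak <- mids[which.max(reg[, "2-back"])]
  expect_gt(t_peak, w$onset[1] + 4)
  expect_lt(t_peak, w$onset[1] + w$duration[1])

  # two identical sessions: the regressor tiles per session
  d1 <- generate_task_design(n_blocks_per_session = 2, n_sessions = 1,
                             rng_seed = 3)
  rows <- as.data.frame(d1)
  rows2 <- rows; rows2$session <- 2L
  d2 <- restshift:::new_task_design(rbind(rows, rows2), n_sessions = 2,
                                    session_duration = attr(d1, "session_duration"))
  sv2 <- session_n_vols(d2, 2.5)
  reg2 <- build_task_regressors(d2, 2.5, 2 * sv2)
  expect_equal(reg2[1:sv2, ], reg2[sv2 + 1:sv2, ], tolerance = 1e-10)

  expect_error(build_task_regressors(d, 2.5, sv + 3), "volumes")
})

test_that("nuisance regression produces orthogonal residuals and matches the OLS oracle", {
  nt <- 30
  v <- tiny_vol(c(3, 3, 3), nt, seed = 4)
  X <- withr::with_seed(5, cbind(a = rnorm(nt), b = rnorm(nt)))
  out <- nuisance_regress(v, X)
  r <- matrix(out$data, 27, nt)
  expect_lt(max(abs(r %*% X[, 1])), 1e-8 * nt)
  expect_lt(max(abs(r %*% X[, 2])), 1e-8 * nt)

  # oracle comparison on one voxel
  y <- v$data[2, 2, 2, ]
  o <- ols_oracle(cbind(1, X), y)
  expect_equal(out$data[2, 2, 2, ], o$resid, tolerance = 1e-10)

  # regressor equal to the series itself -> residual 0
  v1 <- tiny_vol(c(2, 2, 2), nt, seed = 6)
  xr <- v1$data[1, 1, 1, ]
  out1 <- nuisance_regress(v1, cbind(xr))
  expect_equal(max(abs(out1$data[1, 1, 1, ])), 0, tolerance = 1e-10)

  expect_error(nuisance_regress(v, cbind(X, X[, 1])), "collinear")
})

test_that("seed extraction matches brute-force sphere membership", {
  sdim <- c(24, 28, 24)
  aff <- make_affine(3, c(-3, -21, -39))
  v <- tiny_vol(sdim, 5, voxel = 3, origin = c(-3, -21, -39), seed = 7)
  centre <- c(33, 21, -3); radius <- 6

  # exhaustive distance-check oracle
  cnt <- 0; sum_ts <- 0
  for (i in 1:sdim[1]) for (j in 1:sdim[2]) for (k in 1:sdim[3]) {
    mm <- as.numeric(aff %*% c(i - 1, j - 1, k - 1, 1))[1:3]
    if (sum((mm - centre)^2) <= radius^2) {
      cnt <- cnt + 1
      sum_ts <- sum_ts + v$data[i, j, k, ]
    }
  }
  expect_gt(cnt, 1)
  expect_equal(extract_seed_ts(v, centre, radius), sum_ts / cnt,
               tolerance = 1e-12)

  # tiny radius falls back to the voxel containing the centre
  ts1 <- extract_seed_ts(v, centre + 0.4, 0.5)
  ijk <- restshift:::nearest_voxel(aff, centre + 0.4)
  expect_equal(ts1, v$data[ijk[1], ijk[2], ijk[3], ])

  # uniform image returns the constant
  u <- vol4d(array(3, c(sdim, 2)), aff, 2.5)
  expect_equal(extract_seed_ts(u, centre, radius), c(3, 3))
})

test_that("preprocessing chains keep confound rows aligned and affine unchanged", {
  cfg <- demo_cohort_config(n_sz = 1, n_hc = 1)
  coh <- generate_cohort(cfg, rng_seed = 3)
  s <- coh$subjects[[1]]
  pr <- preprocess_rest(s$rest, s$confounds_rest)
  expect_equal(dim(pr$vol$data)[4], nrow(pr$confounds$motion))
  expect_equal(pr$vol$affine, s$rest$affine)
  # residual orthogonality against the confound columns
  keep_rows <- 6:dim(s$rest$data)[4]
  Xc <- cbind(pr$confounds$motion, pr$confounds$global, pr$confounds$wm,
              pr$confounds$csf)
  m <- matrix(pr$vol$data, prod(dim(pr$vol$data)[1:3]), ncol = length(keep_rows))
  dots <- abs(m[100, , drop = FALSE] %*% scale(Xc, scale = FALSE))
  expect_lt(max(dots), 1e-6 * length(keep_rows))

  pt <- preprocess_task(s$task, s$confounds_task, coh$design)
  expect_equal(dim(pt$vol$data)[4], dim(s$task$data)[4])
  expect_equal(pt$vol$affine, s$task$affine)
})
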