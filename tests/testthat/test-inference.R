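make_maps <- function(n, sdim = c(8, 8, 8), mask = NULL, signal = NULL,
                      seed = 1, sd = 1) {
  mask <- mask %||% array(TRUE, sdim)
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    vals <- array(rnorm(prod(sdim), 0, sd), sdim)
    if (!is.null(signal)) vals <- vals + signal(i)
    structure(list(values = vals, direction = "seed_to_brain",
                   affine = make_affine(3), mask = mask, n_blocks = 14L),
              class = "cpc_map")
  }))
}

fake_participants <- function(n_sz, n_hc, seed = 2) {
  withr::with_seed(seed, tibble::tibble(
    id = sprintf("s%02d", seq_len(n_sz + n_hc)),
    group = c(rep("SZ", n_sz), rep("HC", n_hc)),
    age = rnorm(n_sz + n_hc, 33, 9),
    gender = sample(c("F", "M"), n_sz + n_hc, TRUE),
    mean_fd_rest = runif(n_sz + n_hc, 0.05, 0.3),
    mean_fd_task = runif(n_sz + n_hc, 0.05, 0.3)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("group design has the documented columns and df bookkeeping", {
  pp <- fake_participants(29, 31)
  X <- group_design(pp)
  expect_equal(colnames(X), c("intercept", "group", "age", "gender",
                              "mean_fd_rest", "mean_fd_task"))
  expect_equal(X[1, "group"], c(group = 1))
  expect_equal(X[60, "group"], c(group = -1))
  # 60 subjects, 6 columns -> df = 54
  maps <- make_maps(60)
  gt <- voxelwise_group_t(maps, X)
  expect_equal(gt$df, 54)
})

test_that("voxelwise group t matches a hand-solved OLS oracle", {
  pp <- fake_participants(4, 4, seed = 3)
  X <- group_design(pp, covariates = "age")
  maps <- make_maps(8, sdim = c(3, 3, 3), seed = 4)
  gt <- voxelwise_group_t(maps, X)
  expect_equal(gt$df, 8 - 3)

  y <- vapply(maps, function(m) m$values[2, 1, 3], numeric(1))
  o <- ols_oracle(unname(X), y)
  t_or <- o$coef[2] / o$se[2]
  expect_equal(gt$t[2, 1, 3], t_or, tolerance = 1e-8)
})

test_that("null group maps reject at the nominal voxel rate", {
  pp <- fake_participants(12, 12, seed = 5)
  X <- group_design(pp)
  sdim <- c(20, 25, 10)                # 5,000 voxels
  maps <- make_maps(24, sdim = sdim, seed = 6)
  gt <- voxelwise_group_t(maps, X)
  rej <- mean(abs(gt$t) > qt(0.995, gt$df))
  expect_gt(rej, 0.005)
  expect_lt(rej, 0.015)
})

test_that("one-sample cluster test covers plain and adjusted modes", {
  expect_error(one_sample_cluster_t(rep(2, 10)), "variance")
  expect_equal(one_sample_cluster_t(rep(c(1, -1), 5))$statistic, 0)

  vals <- withr::with_seed(7, rnorm(31, 0.3, 1))
  out <- one_sample_cluster_t(vals)
  expect_equal(out$df, 30)
  expect_equal(out$statistic, unname(t.test(vals)$statistic))
  expect_equal(out$p, t.test(vals)$p.value)

  covs <- withr::with_seed(8, cbind(rnorm(31), rnorm(31)))
  out2 <- one_sample_cluster_t(vals, covs)
  expect_equal(out2$df, 31 - 3)
})

test_that("smoothness estimator tracks the applied kernel", {
  sdim <- c(20, 20, 20)
  white <- withr::with_seed(9, lapply(1:20, function(i) {
    array(rnorm(prod(sdim)), sdim)
  }))
  mask <- array(TRUE, sdim)
  fw_white <- estimate_smoothness(white, mask, 3)
  expect_true(all(fw_white >= 3))
  expect_true(all(fw_white < 3 * 1.2))   # white noise ~ voxel size

  smoothed <- withr::with_seed(10, lapply(1:50, function(i) {
    restshift:::smooth_array(array(rnorm(prod(sdim)), sdim), 8, 3)
  }))
  fw_sm <- estimate_smoothness(smoothed, mask, 3)
  expect_true(all(fw_sm > 6.5))
  expect_true(all(fw_sm < 9.5))

  # doubling voxel size doubles the estimate (units)
  fw_doubled <- estimate_smoothness(smoothed, mask, 6)
  expect_equal(fw_doubled, 2 * fw_sm, tolerance = 1e-10)
})

test_that("extent threshold is 1 for isolated ultra-rare voxels", {
  mask <- array(TRUE, c(4, 4, 4))
  out <- alphasim_extent_threshold(mask, fwhm = 0, voxel_p = 1e-6,
                                   alpha = 0.05, n_iter = 1000,
                                   rng_seed = 11)
  expect_equal(out$extent_threshold, 1L)
  expect_length(out$null_max_extent, 1000)
})

test_that("extent threshold controls familywise error on matched nulls", {
  mask <- ellipsoid_mask(c(12, 12, 12))
  fw <- 6
  al <- alphasim_extent_threshold(mask, fw, voxel_p = 0.01, alpha = 0.05,
                                  n_iter = 600, rng_seed = 12)
  k <- al$extent_threshold
  zc <- qnorm(1 - 0.01 / 2)
  inmask <- which(mask)
  fp <- withr::with_seed(13, vapply(1:300, function(i) {
    noise <- restshift:::smooth_array(array(rnorm(12^3), c(12, 12, 12)), fw, 3)
    z <- (noise[inmask] - mean(noise[inmask])) / sd(noise[inmask])
    any_big <- FALSE
    for (sgn in c(1, -1)) {
      sel <- inmask[sgn * z >= zc]
      if (length(sel)) {
        sz <- restshift:::component_sizes(sel, c(12, 12, 12), 26)
        if (max(sz) >= k) any_big <- TRUE
      }
    }
    any_big
  }, logical(1)))
  expect_lte(mean(fp), 0.08)
})

test_that("extent threshold moves monotonically with voxel_p and fwhm", {
  mask <- ellipsoid_mask(c(12, 12, 12))
  k_strict <- alphasim_extent_threshold(mask, 6, voxel_p = 0.001,
                                        n_iter = 400, rng_seed = 14)$extent_threshold
  k_loose <- alphasim_extent_threshold(mask, 6, voxel_p = 0.05,
                                       n_iter = 400, rng_seed = 14)$extent_threshold
  expect_lte(k_strict, k_loose)
  k_smooth <- alphasim_extent_threshold(mask, 10, voxel_p = 0.01,
                                        n_iter = 400, rng_seed = 14)$extent_threshold
  k_rough <- alphasim_extent_threshold(mask, 3, voxel_p = 0.01,
                                       n_iter = 400, rng_seed = 14)$extent_threshold
  expect_gte(k_smooth, k_rough)
})

test_that("cluster extraction finds planted blobs and separates signs", {
  sdim <- c(12, 12, 12)
  tarr <- array(0, sdim)
  mask <- array(TRUE, sdim)
  # 40-voxel positive blob
  blob <- as.matrix(expand.grid(3:6, 3:7, 3:4))
  for (r in seq_len(nrow(blob))) tarr[blob[r, 1], blob[r, 2], blob[r, 3]] <- 6
  # distant negative blob
  tarr[9:10, 9:10, 9:10] <- -6
  cl <- extract_clusters(tarr, voxel_p = 0.01, extent_threshold = 20,
                         df = 54, mask = mask, affine = make_affine(3))
  expect_equal(nrow(cl), 1)            # negative blob (8 voxels) below extent
  expect_equal(cl$extent, 40)
  expect_equal(cl$sign, "SZ>HC")
  expect_equal(cl$peak_t, 6)

  cl2 <- extract_clusters(tarr, voxel_p = 0.01, extent_threshold = 1,
                          df = 54, mask = mask, affine = make_affine(3))
  expect_equal(nrow(cl2), 2)
  expect_setequal(cl2$sign, c("SZ>HC", "SZ<HC"))

  # all-zero map: empty table
  cl0 <- extract_clusters(array(0, sdim), voxel_p = 0.01,
                          extent_threshold = 1, df = 54, mask = mask,
                          affine = make_affine(3))
  expect_equal(nrow(cl0), 0)
})

test_that("connected-component labelling respects connectivity", {
  sdim <- c(5, 5, 5)
  # voxels (1,1,1) and (2,2,2): touching only through a 3D diagonal
  idx <- c(1, 2 + 5 * 1 + 25 * 1)                        # linear: 1 and 32
  lab6 <- restshift:::label_components(idx, sdim, 6)
  expect_equal(max(lab6$membership), 2)
  lab26 <- restshift:::label_components(idx, sdim, 26)
  expect_equal(max(lab26$membership), 1)
})

test_that("cluster means and Cohen's d conversion are exact", {
  maps <- make_maps(5, sdim = c(3, 3, 3), seed = 15)
  vox <- c(2, 14, 27)
  means <- cluster_mean_cpc(maps, vox)
  # 3-voxel arithmetic oracle
  expect_equal(means[2], mean(maps[[2]]$values[vox]))
  expect_equal(cluster_mean_cpc(maps, 5),
               vapply(maps, function(m) m$values[5], numeric(1)))

  expect_equal(round(cohens_d_from_t(4.72, 29, 31), 2), 1.22)
  expect_equal(round(cohens_d_from_t(-3.88, 29, 31), 2), -1.00)
  expect_equal(cohens_d_from_t(0, 10, 10), 0)
})

test_that("activation control adjusts the group test appropriately", {
  pp <- fake_participants(6, 6, seed = 16)
  X <- group_design(pp, covariates = "age")
  withr::local_seed(17)
  cpc <- X[, "group"] * 0.5 + rnorm(12, 0, 0.3)

  # activation orthogonal to design and outcome leaves the coefficient
  # untouched; t changes only through the lost error df
  act <- resid(lm(rnorm(12) ~ X + cpc - 1))
  t_unadj <- restshift:::cluster_group_t(cpc, X)$statistic
  t_adj <- activation_control(cpc, act, X)$statistic
  df1 <- 12 - ncol(X); df2 <- df1 - 1
  expect_equal(t_adj, t_unadj * sqrt(df2 / df1), tolerance = 1e-6)

  # CPC (nearly) fully explained by activation: group effect collapses
  act2 <- cpc + rnorm(12, 0, 0.02)
  t_med <- activation_control(cpc, act2, X)$statistic
  expect_lt(abs(t_med), abs(t_unadj))

  # oracle check on a 12-subject fixture
  y <- rnorm(12)
  a3 <- rnorm(12)
  o <- ols_oracle(unname(cbind(X, a3)), y)
  expect_equal(activation_control(y, a3, X)$statistic, o$coef[2] / o$se[2],
               tolerance = 1e-8)
})
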