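test_that("path coefficient matches the normal-equations oracle", {
  # fixed 8-point pair, solved independently by lm()
  x <- c(0.2, -1.1, 0.7, 1.9, -0.4, 0.8, -1.5, 0.3)
  y <- c(1.0, 0.1, -0.7, 0.4, 1.2, -0.9, 0.5, -0.2)
  expect_equal(path_coefficient(x, y), pc_oracle(x, y), tolerance = 1e-10)

  # exact lag copy (circular, so both series share identical moments):
  # coefficient 1, z-scoring preserves the unit slope
  xw <- withr::with_seed(1, rnorm(100))
  yw <- xw[c(100, 1:99)]
  expect_equal(path_coefficient(xw, yw), 1, tolerance = 1e-6)

  # independent white noise: mean coefficient near 0 over 200 reps
  est <- withr::with_seed(2, vapply(1:200, function(i) {
    path_coefficient(rnorm(235), rnorm(235))
  }, numeric(1)))
  expect_lt(abs(mean(est)), 0.02)

  expect_error(path_coefficient(rep(1, 20), rnorm(20)), "constant")
  expect_error(path_coefficient(rnorm(3), rnorm(3)), "short")
})

test_that("exchange symmetry: swapping the series swaps the direction", {
  x <- withr::with_seed(3, rnorm(50))
  y <- withr::with_seed(4, rnorm(50))
  expect_equal(path_coefficient(x, y), pc_oracle(x, y))
  expect_equal(path_coefficient(y, x), pc_oracle(y, x))
  expect_false(isTRUE(all.equal(path_coefficient(x, y),
                                path_coefficient(y, x))))
})

test_that("path-coefficient t statistic is calibrated under the null", {
  res <- withr::with_seed(5, vapply(1:1000, function(i) {
    path_coefficient(rnorm(235), rnorm(235), details = TRUE)$t
  }, numeric(1)))
  rej <- mean(abs(res) > qt(0.975, 235 - 1 - 3))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("estimator is consistent on long VAR(1) series", {
  spec <- two_node_spec(b = 0.4, a = 0.3)
  d <- generate_task_design(rng_seed = 1)
  sim <- simulate_var_system(spec, d, n_rest_vols = 10000, rng_seed = 6)
  x <- sim$rest[, "seed"]; y <- sim$rest[, "target"]
  # standardized regression coefficient implied by the VAR
  b_std <- 0.4 * sd(x) / sd(y)
  expect_lt(abs(path_coefficient(x, y) - b_std), 0.02)
})

test_that("seed PC maps recover direction-specific structure", {
  sdim <- c(8, 8, 8); nt <- 120
  seed_ts <- withr::with_seed(7, rnorm(nt))
  # every voxel equals the seed shifted by one TR -> seed_to_brain map ~ 1
  lagged <- c(0, seed_ts[-nt])
  dat <- array(rep(lagged, each = prod(sdim)), c(sdim, nt))
  # add minute jitter so voxels are not exactly collinear
  dat <- dat + withr::with_seed(8, array(rnorm(length(dat), 0, 1e-4),
                                         dim(dat)))
  v <- vol4d(dat, make_affine(3), 2.5)
  m <- seed_pc_map(v, seed_ts, "seed_to_brain")
  expect_true(all(abs(m$values - 1) < 0.01))

  # independent noise volume: map mean ~ 0, SD ~ OLS standard error
  vn <- tiny_vol(c(10, 10, 10), 235, seed = 9)
  mn <- seed_pc_map(vn, withr::with_seed(10, rnorm(235)), "seed_to_brain")
  expect_lt(abs(mean(mn$values)), 0.02)
  expect_equal(sd(mn$values), 1 / sqrt(235), tolerance = 0.25)

  # brain_to_seed is a different regression, not the transpose
  mb <- seed_pc_map(vn, withr::with_seed(10, rnorm(235)), "brain_to_seed")
  expect_false(isTRUE(all.equal(mn$values, mb$values)))
})

test_that("blockwise task PC averages per-block estimates", {
  d <- generate_task_design(rng_seed = 1)
  sv <- session_n_vols(d, 2.5)
  nt <- sv * 2
  v <- tiny_vol(c(4, 4, 4), nt, seed = 11)
  seed_ts <- withr::with_seed(12, rnorm(nt))
  m <- blockwise_task_pc(v, seed_ts, d, direction = "seed_to_brain")
  expect_equal(m$n_blocks, 14)

  # per-block oracle then arithmetic mean, for one voxel
  blocks <- restshift:::condition_block_indices(d, 2.5, nt, "2-back")
  per_block <- vapply(blocks, function(ix) {
    ys <- v$data[2, 3, 1, ix]; xs <- seed_ts[ix]
    tt <- seq_along(ix)
    ydt <- resid(lm(ys ~ tt)); xdt <- resid(lm(xs ~ tt))
    pc_oracle(xdt / sd(xdt), ydt / sd(ydt))
  }, numeric(1))
  expect_equal(m$values[2, 3, 1], mean(per_block), tolerance = 1e-8)

  # short blocks are dropped with a warning; losing all blocks is an error
  rows <- data.frame(label = "2-back", onset = c(0, 110, 220),
                     duration = c(30, 30, 10), session = 1L)
  d_short <- restshift:::new_task_design(rows, n_sessions = 1,
                                         session_duration = 770)
  sv1 <- session_n_vols(d_short, 2.5)
  v1 <- tiny_vol(c(3, 3, 3), sv1, seed = 20)
  s1 <- withr::with_seed(21, rnorm(sv1))
  expect_warning(
    m1 <- blockwise_task_pc(v1, s1, d_short, direction = "seed_to_brain"),
    "dropped")
  expect_equal(m1$n_blocks, 2)
  expect_error(
    suppressWarnings(blockwise_task_pc(v1, s1, d_short,
                                       direction = "seed_to_brain",
                                       min_block_vols = 13)),
    "no usable")
})

test_that("CPC map is the voxelwise task-minus-rest difference", {
  v <- tiny_vol(c(4, 4, 4), 60, seed = 13)
  s <- withr::with_seed(14, rnorm(60))
  pc_r <- seed_pc_map(v, s, "seed_to_brain", state = "rest")
  pc_t <- seed_pc_map(v, s, "seed_to_brain", state = "task")
  cc <- cpc_map(pc_t, pc_r)
  expect_true(all(cc$values == 0))

  pc_b <- seed_pc_map(v, s, "brain_to_seed")
  expect_error(cpc_map(pc_b, pc_r), "direction")
})

test_that("CPC sign convention: larger task influence gives positive CPC", {
  # planted edge b_rest = 0, b_task = 0.4: cohort-mean CPC in [0.25, 0.55]
  spec <- two_node_spec(b = 0.4, b_rest = 0)
  A_task <- spec$A_rest; A_task[2, 1] <- 0.4
  d <- generate_task_design(rng_seed = 1)
  cpcs <- withr::with_seed(15, vapply(1:20, function(i) {
    sim <- simulate_var_system(spec, d, n_rest_vols = 235, A_task = A_task)
    pc_rest <- path_coefficient(sim$rest[, 1], sim$rest[, 2])
    blocks <- restshift:::condition_block_indices(d, 2.5, nrow(sim$task),
                                                  "2-back")
    pc_task <- mean(vapply(blocks, function(ix) {
      tt <- seq_along(ix)
      x <- resid(lm(sim$task[ix, 1] ~ tt)); y <- resid(lm(sim$task[ix, 2] ~ tt))
      path_coefficient(x, y)
    }, numeric(1)))
    pc_task - pc_rest
  }, numeric(1)))
  expect_gt(mean(cpcs), 0.25)
  expect_lt(mean(cpcs), 0.55)
})

test_that("functional-connectivity change map matches the direct correlation oracle", {
  d <- generate_task_design(rng_seed = 1)
  sv <- session_n_vols(d, 2.5); nt <- sv * 2
  vr <- tiny_vol(c(4, 4, 4), 100, seed = 16)
  vt <- tiny_vol(c(4, 4, 4), nt, seed = 17)
  sr <- withr::with_seed(18, rnorm(100))
  st <- withr::with_seed(19, rnorm(nt))
  fc <- fc_change_map(vr, vt, sr, st, d)

  # oracle at one voxel
  r_rest <- cor(vr$data[1, 2, 3, ], sr)
  blocks <- restshift:::condition_block_indices(d, 2.5, nt, "2-back")
  r_task <- mean(vapply(blocks, function(ix) {
    tt <- seq_along(ix)
    cor(resid(lm(vt$data[1, 2, 3, ix] ~ tt)), resid(lm(st[ix] ~ tt)))
  }, numeric(1)))
  expect_equal(fc$values[1, 2, 3], r_task - r_rest, tolerance = 1e-12)

  # voxel equal to the seed: rest correlation is 1
  vt2 <- vr
  vt2$data[1, 1, 1, ] <- sr
  r <- cor(vt2$data[1, 1, 1, ], sr)
  expect_equal(r, 1)
})
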