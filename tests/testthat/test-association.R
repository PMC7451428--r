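test_that("correlation p values follow the t approximation", {
  # r = 0.478, n = 31 -> p = 0.0065; r = 0.3765, n = 29 -> p = 0.0441
  p_from_r <- function(r, n) {
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * pt(-abs(tt), n - 2)
  }
  expect_equal(round(p_from_r(0.478, 31), 4), 0.0065)
  expect_lt(abs(p_from_r(0.3765, 29) - 0.0441), 5e-4)

  # correlate() reproduces those p values from data constructed to the r
  make_xy <- function(r, n, seed) {
    withr::with_seed(seed, {
      x <- rnorm(n); e <- rnorm(n)
      e <- resid(lm(e ~ x))
      xs <- as.numeric(scale(x)); es <- as.numeric(scale(e))
      list(x = xs, y = r * xs + sqrt(1 - r^2) * es)
    })
  }
  d <- make_xy(0.478, 31, 1)
  out <- correlate(d$x, d$y, "pearson")
  expect_equal(out$r, 0.478, tolerance = 1e-10)
  expect_equal(round(out$p, 4), 0.0065)
  expect_equal(out$df, 29)

  # matches cor.test (pearson) as an independent implementation
  ct <- cor.test(d$x, d$y)
  expect_equal(out$p, ct$p.value, tolerance = 1e-12)
})

test_that("Spearman equals Pearson on average ranks, ties included", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  out <- correlate(x, y, "spearman")
  expect_equal(out$r, cor(rank(x), rank(y)))
  expect_equal(out$method, "spearman")
  # y = x gives r = 1
  expect_equal(correlate(x, x + 0, "spearman")$r, 1)
})

test_that("partial correlation with no covariates equals plain correlation", {
  withr::local_seed(2)
  x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  plain <- correlate(x, y)
  part0 <- correlate(x, y, covariates = NULL)
  expect_equal(plain$r, part0$r)

  part <- correlate(x, y, covariates = cbind(z))
  expect_equal(part$df, 20 - 3)
  # oracle: correlation of lm residuals
  rx <- resid(lm(x ~ z)); ry <- resid(lm(y ~ z))
  expect_equal(part$r, cor(rx, ry), tolerance = 1e-12)
})

test_that("Fisher r-to-Z comparison matches the closed-form oracle", {
  # closed-form oracle computed inline
  z_or <- (atanh(0.478) - atanh(0)) / sqrt(1 / (31 - 3) + 1 / (29 - 3))
  out <- fisher_r_to_z_compare(0.478, 31, 0, 29)
  expect_equal(out$z, z_or, tolerance = 1e-12)
  expect_equal(out$p, pnorm(z_or, lower.tail = FALSE), tolerance = 1e-12)

  # equal correlations: z = 0, one-tailed p = 0.5
  eq <- fisher_r_to_z_compare(0.3, 40, 0.3, 25)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 0.5)

  # antisymmetry
  a <- fisher_r_to_z_compare(0.5, 30, 0.2, 28)
  b <- fisher_r_to_z_compare(0.2, 28, 0.5, 30)
  expect_equal(a$z, -b$z)

  expect_error(fisher_r_to_z_compare(1, 30, 0.2, 28), "below 1")
})

test_that("demographic chi-squares reproduce the published table values", {
  gender <- rbind(SZ = c(F = 5, M = 24), HC = c(F = 9, M = 22))
  expect_equal(round(chi_square_2x2(gender)$statistic, 2), 1.16)
  handed <- rbind(SZ = c(L = 5, R = 24), HC = c(L = 3, R = 28))
  expect_equal(round(suppressWarnings(chi_square_2x2(handed))$statistic, 2),
               0.74)

  # equal proportions give 0
  eqt <- rbind(c(10, 20), c(5, 10))
  expect_equal(chi_square_2x2(eqt)$statistic, 0)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(1, 2))), "margins")
})

test_that("chi-square agrees with brute-force expected counts", {
  # exhaustive over a grid of tables with margins <= 50
  withr::local_seed(3)
  for (i in 1:50) {
    tab <- matrix(sample(1:25, 4, TRUE), 2, 2)
    o <- suppressWarnings(chi_square_2x2(tab)$statistic)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(o, sum((tab - E)^2 / E), tolerance = 1e-12)
  }
})

test_that("summary-statistics t test reproduces the hit-rate comparison", {
  out <- two_sample_t_summary(78.5, 5.0, 31, 73.7, 7.5, 29)
  expect_equal(out$df, 58)
  expect_gt(abs(out$statistic), 2.8)
  expect_lt(abs(out$statistic), 3.0)

  expect_equal(two_sample_t_summary(5, 1, 10, 5, 2, 12)$statistic, 0)

  # 5-vs-5 arithmetic oracle
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10)
  o <- two_sample_t_summary(mean(x), sd(x), 5, mean(y), sd(y), 5)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(o$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(o$p, tt$p.value, tolerance = 1e-12)
})

test_that("p values are invariant to group relabelling", {
  tab <- rbind(c(7, 13), c(11, 9))
  expect_equal(chi_square_2x2(tab)$p, chi_square_2x2(tab[2:1, ])$p)
  a <- two_sample_t_summary(10, 2, 15, 12, 3, 18)
  b <- two_sample_t_summary(12, 3, 18, 10, 2, 15)
  expect_equal(a$p, b$p)
  expect_equal(a$statistic, -b$statistic)
})

test_that("association battery runs the configured tests with thresholds", {
  cfg <- demo_cohort_config()
  coh <- generate_cohort(cfg, rng_seed = 4, volumes = FALSE)
  pp <- coh$participants
  cm <- data.frame(clusterA = coh$ground_truth$subjects$true_cpc +
                     rnorm(nrow(pp), 0, 0.05))
  out <- association_battery(cm, pp)
  expect_s3_class(out, "tbl_df")
  expect_true(all(c("cluster", "variable", "group", "method", "estimate",
                    "p", "threshold", "significant") %in% names(out)))
  # hypothesis-specific thresholds
  expect_equal(unique(out$threshold[out$variable == "psychomotor_poverty"]),
               0.025)
  expect_equal(unique(out$threshold[out$variable == "hit_rate" &
                                      out$method == "spearman"]), 0.05)
  # hit rate tested in both groups plus a Fisher comparison
  hr <- out[out$variable == "hit_rate", ]
  expect_setequal(hr$group, c("HC", "SZ", "HC-vs-SZ"))
  # SZ-only scores never tested in HC
  expect_false("HC" %in% out$group[out$variable == "sofas"])

  pp_broken <- pp[, setdiff(names(pp), "sofas")]
  expect_error(association_battery(cm, pp_broken), "sofas")
})

test_that("association false-positive rate matches the nominal threshold", {
  # all-noise scores: per-test rejection ~ alpha
  withr::local_seed(5)
  n <- 40
  reps <- 200
  fp <- vapply(seq_len(reps), function(i) {
    x <- rnorm(n); y <- rnorm(n)
    correlate(x, y, "spearman")$p < 0.05
  }, logical(1))
  expect_gt(mean(fp), 0.02)
  expect_lt(mean(fp), 0.09)
})
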