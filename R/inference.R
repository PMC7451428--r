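#' Group-comparison design matrix
#'
#' Builds the covariate-adjusted two-sample design: intercept, group
#' contrast (SZ = +1, HC = -1), age, gender (F = 1, M = 0), and the two
#' mean-FD motion covariates (rest and task). With the full sample of 60
#' subjects this leaves 60 - 6 = 54 error degrees of freedom.
#'
#' @param participants Tibble with columns `group`, `age`, `gender`,
#'   `mean_fd_rest`, `mean_fd_task`.
#' @param covariates Character vector naming which covariate columns to
#'   include alongside intercept and group.
#' @return Numeric design matrix with named columns.
#' @export
group_design <- function(participants,
                         covariates = c("age", "gender", "mean_fd_rest",
                                        "mean_fd_task")) {
  stopifnot(all(c("group", covariates) %in% names(participants)))
  g <- ifelse(participants$group == "SZ", 1, -1)
  X <- cbind(intercept = 1, group = g)
  for (cv in covariates) {
    col <- participants[[cv]]
    if (cv == "gender") col <- ifelse(col == "F", 1, 0)
    X <- cbind(X, as.numeric(col))
    colnames(X)[ncol(X)] <- cv
  }
  if (qr(X)$rank < ncol(X)) stop("group design is rank deficient")
  X
}

#' Voxelwise covariate-adjusted group t-map
#'
#' Fits, at every in-mask voxel, the OLS model `CPC ~ design` across
#' subjects and returns the t-statistic of the group-contrast column with
#' `df = n - p` error degrees of freedom, together with the residual maps
#' needed for smoothness estimation.
#'
#' @param cpc_maps List of per-subject `cpc_map`s (same grid and order as
#'   the design rows).
#' @param design Design matrix from [group_design()]; must contain a
#'   `group` column.
#' @param term Column whose t-statistic is mapped.
#' @return A `group_t_map`: list with `t` (3D array), `df`, `residuals`
#'   (`n x V_mask`), `mask`, `affine`, `n`.
#' @export
voxelwise_group_t <- function(cpc_maps, design, term = "group") {
  stopifnot(length(cpc_maps) >= 3)
  X <- as.matrix(design)
  if (!term %in% colnames(X)) stop("design has no '", term, "' column")
  if (nrow(X) != length(cpc_maps)) stop("design rows must match number of maps")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("group design is rank deficient")
  ref <- cpc_maps[[1]]
  mask <- ref$mask
  inmask <- which(as.logical(mask))
  Y <- vapply(cpc_maps, function(m) {
    if (!identical(dim(m$values), dim(ref$values))) stop("map grid mismatch")
    m$values[inmask]
  }, numeric(length(inmask)))
  Y <- t(Y)                                    # n x V
  n <- nrow(Y); p <- ncol(X); df <- n - p
  if (df < 1) stop("not enough subjects for the design")
  coefs <- qr.coef(qx, Y)
  resid <- qr.resid(qx, Y)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qx))
  j <- match(term, colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  tval <- ifelse(se > 0, coefs[j, ] / se, 0)
  tmap <- array(NA_real_, dim(ref$values))
  tmap[inmask] <- tval
  structure(list(t = tmap, df = df, residuals = resid, mask = mask,
                 affine = ref$affine, n = n, term = term),
            class = "group_t_map")
}

#' @export
print.group_t_map <- function(x, ...) {
  cat(sprintf("<group_t_map> n = %d, df = %d, max |t| = %.2f\n",
              x$n, x$df, max(abs(x$t), na.rm = TRUE)))
  invisible(x)
}

#' One-sample t-test of cluster-mean CPCs
#'
#' Plain mode is the classical one-sample t (`df = n - 1`); adjusted mode
#' regresses the values on mean-centred covariates and tests the intercept
#' (`df = n - 1 - k`), asking whether the group-mean CPC differs from zero
#' after covariate adjustment.
#'
#' @param values Per-subject cluster-mean CPCs (`n >= 3`).
#' @param covariates Optional numeric matrix of covariates (adjusted mode).
#' @return A one-row tibble: `statistic`, `df`, `p`, `d` (one-sample
#'   Cohen's d, mean/SD).
#' @export
one_sample_cluster_t <- function(values, covariates = NULL) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  if (stats::sd(values) == 0) stop("zero variance")
  if (is.null(covariates)) {
    tt <- mean(values) / (stats::sd(values) / sqrt(n))
    df <- n - 1
  } else {
    Z <- scale(as.matrix(covariates), scale = FALSE)
    fit <- stats::lm(values ~ Z)
    sm <- summary(fit)$coefficients
    tt <- sm["(Intercept)", "t value"]
    df <- fit$df.residual
  }
  tibble::tibble(statistic = tt, df = df,
                 p = 2 * stats::pt(-abs(tt), df),
                 d = mean(values) / stats::sd(values))
}

#' Estimate map smoothness (FWHM) from residuals
#'
#' Classical first-difference estimator: per axis,
#' `FWHM = voxel_size * sqrt(-2 ln 2 / ln(1 - var(diff) / (2 var)))`,
#' where `var(diff)` is the variance of first differences between in-mask
#' neighbours and `var` the map variance, averaged across residual maps
#' and clamped to at least one voxel.
#'
#' @param residuals `n x V_mask` matrix (as in `group_t_map$residuals`) or
#'   a list of 3D arrays.
#' @param mask 3D logical mask (required for the matrix form).
#' @param voxel_size Voxel edge lengths in mm (length 1 or 3).
#' @return Numeric length-3 vector of per-axis FWHM (mm).
#' @export
estimate_smoothness <- function(residuals, mask, voxel_size = 3) {
  voxel_size <- rep_len(voxel_size, 3)
  sdim <- dim(mask)
  inmask <- which(as.logical(mask))
  if (is.matrix(residuals)) {
    maps <- lapply(seq_len(nrow(residuals)), function(i) {
      a <- array(NA_real_, sdim); a[inmask] <- residuals[i, ]; a
    })
  } else maps <- residuals
  if (length(maps) < 2) stop("need at least 2 residual maps")

  fwhm_axis <- matrix(NA_real_, length(maps), 3)
  for (i in seq_along(maps)) {
    a <- maps[[i]]
    vals <- a[inmask]
    v0 <- stats::var(vals)
    if (!is.finite(v0) || v0 == 0) stop("constant residual map")
    for (ax in 1:3) {
      d <- axis_diff(a, ax)
      dv <- d[is.finite(d)]
      if (!length(dv)) next
      ratio <- stats::var(dv) / (2 * v0)
      fw <- if (ratio >= 1 || ratio <= 0) voxel_size[ax] else {
        voxel_size[ax] * sqrt(-2 * log(2) / log(1 - ratio))
      }
      fwhm_axis[i, ax] <- max(fw, voxel_size[ax])
    }
  }
  out <- colMeans(fwhm_axis, na.rm = TRUE)
  pmax(out, voxel_size)
}

axis_diff <- function(a, ax) {
  d <- dim(a)
  idx1 <- lapply(d, seq_len)
  idx2 <- idx1
  idx1[[ax]] <- seq_len(d[ax] - 1)
  idx2[[ax]] <- 2:d[ax]
  do.call(`[`, c(list(a), idx2)) - do.call(`[`, c(list(a), idx1))
}

#' Monte-Carlo cluster-extent threshold (AlphaSim-style)
#'
#' Estimates the null distribution of the maximum suprathreshold cluster
#' size in smooth Gaussian noise on the analysis mask: each iteration
#' simulates white noise on the grid, smooths it to the target FWHM,
#' re-standardises within the mask, applies the two-sided voxel threshold,
#' and records the largest connected component (positive and negative
#' excursions labelled separately). The returned extent threshold is the
#' smallest cluster size whose familywise probability under the null is at
#' most `alpha`.
#'
#' @param mask 3D logical analysis mask.
#' @param fwhm Noise smoothness in mm (scalar or per-axis).
#' @param voxel_p Two-sided voxel-level p threshold.
#' @param alpha Cluster-level familywise alpha.
#' @param n_iter Monte-Carlo iterations (>= 200).
#' @param connectivity 6, 18 or 26.
#' @param voxel_size Voxel size in mm.
#' @param rng_seed Optional seed.
#' @return List with `extent_threshold` (voxels) and `null_max_extent`
#'   (length `n_iter`).
#' @export
alphasim_extent_threshold <- function(mask, fwhm, voxel_p = 0.01,
                                      alpha = 0.05, n_iter = 1000,
                                      connectivity = 26, voxel_size = 3,
                                      rng_seed = NULL) {
  sdim <- dim(mask)
  inmask <- which(as.logical(mask))
  if (!length(inmask)) stop("mask is empty")
  if (voxel_p <= 0 || voxel_p >= 1 || alpha <= 0 || alpha >= 1) {
    stop("voxel_p and alpha must lie in (0, 1)")
  }
  if (n_iter < 200) stop("n_iter must be at least 200")
  fwhm <- rep_len(fwhm, 3)
  voxel_size <- rep_len(voxel_size, 3)
  zcrit <- stats::qnorm(1 - voxel_p / 2)

  null_max <- with_seed(rng_seed, {
    vapply(seq_len(n_iter), function(it) {
      noise <- array(stats::rnorm(prod(sdim)), sdim)
      noise <- smooth_array(noise, fwhm, voxel_size)
      vals <- noise[inmask]
      z <- (vals - mean(vals)) / stats::sd(vals)
      mx <- 0L
      for (sgn in c(1, -1)) {
        sel <- inmask[sgn * z >= zcrit]
        if (length(sel)) {
          sizes <- component_sizes(sel, sdim, connectivity)
          mx <- max(mx, sizes)
        }
      }
      as.integer(mx)
    }, integer(1))
  })

  k <- 1L
  while (mean(null_max >= k) > alpha) k <- k + 1L
  list(extent_threshold = k, null_max_extent = null_max)
}

# connected components of a sparse voxel index set (compiled BFS over the
# suprathreshold set; 6/18/26-neighbour)
label_components <- function(idx, sdim, connectivity = 26) {
  m <- length(idx)
  if (m == 0) return(list(membership = integer(0), sizes = integer(0)))
  stopifnot(connectivity %in% c(6, 18, 26))
  membership <- .label_components_cpp(as.integer(idx), as.integer(sdim),
                                      as.integer(connectivity))
  list(membership = membership, sizes = tabulate(membership))
}

component_sizes <- function(idx, sdim, connectivity = 26) {
  label_components(idx, sdim, connectivity)$sizes
}

#' Extract suprathreshold clusters into a cluster table
#'
#' Applies the two-sided voxel threshold `|t| >= t_{voxel_p/2, df}`, labels
#' connected components separately for positive and negative excursions,
#' discards components smaller than the extent threshold, and reports each
#' surviving cluster with its size, peak t, and peak location in mm.
#'
#' @param t_map A `group_t_map` (or 3D t array with `df`, `mask`, `affine`
#'   supplied).
#' @param voxel_p Two-sided voxel-level p threshold.
#' @param extent_threshold Minimum cluster extent in voxels.
#' @param connectivity 6, 18 or 26.
#' @param df,mask,affine Required when `t_map` is a bare array.
#' @param null_max_extent Optional null distribution from
#'   [alphasim_extent_threshold()] used to attach cluster-level p values.
#' @return A tibble (`cluster_table`): `label`, `sign`, `extent`, `peak_t`,
#'   `peak_x`, `peak_y`, `peak_z`, `cluster_p`, and a `voxels` list-column
#'   of linear indices.
#' @export
extract_clusters <- function(t_map, voxel_p = 0.01, extent_threshold = 1,
                             connectivity = 26, df = NULL, mask = NULL,
                             affine = NULL, null_max_extent = NULL) {
  if (inherits(t_map, "group_t_map")) {
    df <- t_map$df; mask <- t_map$mask; affine <- t_map$affine
    tarr <- t_map$t
  } else {
    tarr <- t_map
    if (is.null(df) || is.null(mask) || is.null(affine)) {
      stop("df, mask and affine are required with a bare t array")
    }
  }
  sdim <- dim(tarr)
  tcrit <- stats::qt(1 - voxel_p / 2, df)
  rows <- list()
  for (sgn in c(1, -1)) {
    sel <- which(as.logical(mask) & is.finite(tarr) & sgn * tarr >= tcrit)
    if (!length(sel)) next
    lab <- label_components(sel, sdim, connectivity)
    for (ci in seq_along(lab$sizes)) {
      if (lab$sizes[ci] < extent_threshold) next
      vox <- sel[lab$membership == ci]
      pk <- vox[which.max(abs(tarr[vox]))]
      mm <- vox_to_mm(affine, arrayInd(pk, sdim) - 1)
      cp <- if (!is.null(null_max_extent)) {
        mean(null_max_extent >= length(vox))
      } else NA_real_
      rows[[length(rows) + 1]] <- tibble::tibble(
        sign = if (sgn > 0) "SZ>HC" else "SZ<HC",
        extent = length(vox), peak_t = tarr[pk],
        peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        cluster_p = cp, voxels = list(vox))
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(sign = character(0), extent = integer(0),
                   peak_t = numeric(0), peak_x = numeric(0),
                   peak_y = numeric(0), peak_z = numeric(0),
                   cluster_p = numeric(0), voxels = list())
  }
  out <- dplyr::arrange(out, dplyr::desc(abs(.data$peak_t)))
  out <- dplyr::mutate(out, label = paste0("cluster", dplyr::row_number()),
                       .before = 1)
  class(out) <- c("cluster_table", class(out))
  out
}

#' Per-subject mean CPC within a cluster
#'
#' @param cpc_maps List of per-subject `cpc_map`s.
#' @param voxels Linear voxel indices of the cluster (e.g. from the
#'   `voxels` list-column of [extract_clusters()]).
#' @return Numeric vector, one mean per subject.
#' @export
cluster_mean_cpc <- function(cpc_maps, voxels) {
  if (!length(voxels)) stop("cluster is empty")
  mask <- cpc_maps[[1]]$mask
  if (any(!mask[voxels])) stop("cluster extends outside the mask")
  vapply(cpc_maps, function(m) mean(m$values[voxels]), numeric(1))
}

#' Two-sample Cohen's d from a t statistic
#'
#' Standard conversion for a two-sample comparison:
#' `d = t * sqrt(1/n1 + 1/n2)`; the sign follows `t`.
#'
#' @param t t statistic.
#' @param n1,n2 Group sizes.
#' @return Cohen's d.
#' @export
cohens_d_from_t <- function(t, n1, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  t * sqrt(1 / n1 + 1 / n2)
}

#' Group test of cluster CPC controlling for brain activation
#'
#' Re-tests the group difference in cluster-mean CPC after appending
#' per-subject task-activation betas (e.g. of the seed region and the
#' cluster) to the covariate set, to check that a connectivity difference
#' is not a by-product of an activation difference.
#'
#' @param cluster_cpc Per-subject cluster-mean CPCs.
#' @param activation_betas Numeric vector or matrix of per-subject
#'   activation betas.
#' @param design Design matrix from [group_design()].
#' @return One-row tibble: `statistic`, `df`, `p`, `d`.
#' @export
activation_control <- function(cluster_cpc, activation_betas, design) {
  X <- cbind(as.matrix(design), act = as.matrix(activation_betas))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("activation covariates are collinear with the design")
  n <- length(cluster_cpc)
  if (nrow(X) != n) stop("design rows must match value count")
  df <- n - ncol(X)
  fit <- stats::lm.fit(X, cluster_cpc)
  XtXinv <- chol2inv(qr.R(qx))
  j <- match("group", colnames(design))
  se <- sqrt(sum(fit$residuals^2) / df * XtXinv[j, j])
  tt <- fit$coefficients[j] / se
  n1 <- sum(design[, "group"] > 0); n2 <- sum(design[, "group"] < 0)
  tibble::tibble(statistic = unname(tt), df = df,
                 p = 2 * stats::pt(-abs(tt), df),
                 d = cohens_d_from_t(unname(tt), n1, n2))
}

#' Per-subject task-activation beta of a region
#'
#' Mean region series regressed on the session-wise confounds plus all
#' condition regressors; returns the coefficient of the requested
#' condition (a per-subject GLM activation estimate, computed on data that
#' has not had the task regressors removed).
#'
#' @param vol A [vol4d()] task scan (smoothed, not task-regressed).
#' @param confounds Matching [confound_set()].
#' @param design Task design.
#' @param voxels Linear voxel indices of the region.
#' @param condition Condition whose beta is returned.
#' @return Scalar beta.
#' @export
activation_beta <- function(vol, confounds, design, voxels,
                            condition = "2-back") {
  stopifnot(inherits(vol, "vol4d"))
  nt <- n_vols(vol)
  v <- prod(dim(vol$data)[1:3])
  series <- colMeans(matrix(vol$data, v, nt)[voxels, , drop = FALSE])
  reg <- build_task_regressors(design, vol$tr, nt)
  sv <- session_n_vols(design, vol$tr)
  ns <- attr(design, "n_sessions")
  sess <- factor(rep(seq_len(ns), each = sv))
  X <- cbind(stats::model.matrix(~sess), confounds$motion,
             global = confounds$global, wm = confounds$wm,
             csf = confounds$csf, reg)
  fit <- stats::lm.fit(X, series)
  unname(fit$coefficients[condition])
}
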