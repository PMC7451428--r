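#' Lag-1 Granger path coefficient between two series
#'
#' The directed influence of `x` on `y` at one time lag: both series are
#' z-scored, then `y_t` is regressed by ordinary least squares on an
#' intercept, its own past `y_{t-lag}` and the source's past `x_{t-lag}`;
#' the returned path coefficient is the `x_{t-lag}` coefficient. On
#' z-scored series it is a standardised regression weight, signed, with
#' magnitude typically below 1.
#'
#' @param x Source series.
#' @param y Target series (same length, `T >= lag + 3`).
#' @param lag Time lag in samples (validated default 1).
#' @param details Return a list with `coef`, `se`, `t`, `df` instead of the
#'   bare coefficient.
#' @return The signed path coefficient, or a list when `details = TRUE`.
#' @export
path_coefficient <- function(x, y, lag = 1, details = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have the same length")
  nt <- length(x)
  if (!is_count(lag)) stop("lag must be a positive integer")
  if (nt < lag + 3) stop("series too short: need T >= lag + 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant series")
  xz <- as.numeric(scale(x))
  yz <- as.numeric(scale(y))
  idx <- (lag + 1):nt
  yt <- yz[idx]; ylag <- yz[idx - lag]; xlag <- xz[idx - lag]
  fit <- stats::lm.fit(cbind(1, ylag, xlag), yt)
  b <- unname(fit$coefficients[3])
  if (!details) return(b)
  df <- length(idx) - 3
  se <- if (df > 0) {
    XtXinv <- chol2inv(chol(crossprod(cbind(1, ylag, xlag))))
    sqrt(sum(fit$residuals^2) / df * XtXinv[3, 3])
  } else NA_real_
  list(coef = b, se = se, t = b / se, df = df)
}

new_pc_map <- function(values, direction, state, affine, mask,
                       n_blocks = NA_integer_, n_degenerate = 0L) {
  structure(list(values = values, direction = direction, state = state,
                 affine = affine, mask = mask, n_blocks = n_blocks,
                 n_degenerate = n_degenerate),
            class = "pc_map")
}

#' @export
print.pc_map <- function(x, ...) {
  cat(sprintf("<pc_map> %s, %s state, %d voxels%s\n", x$direction, x$state,
              sum(x$mask),
              if (!is.na(x$n_blocks)) sprintf(", %d blocks", x$n_blocks) else ""))
  invisible(x)
}

# Closed-form per-voxel coefficient of x in OLS of y on [1, a, x].
# Each argument is either a vector (common) or a T x V matrix (per voxel);
# all are centred internally. Returns a list(b, denom_ok).
fwl_coefficient <- function(y, a, x) {
  centre <- function(m) if (is.matrix(m)) {
    sweep(m, 2, colMeans(m))
  } else m - mean(m)
  y <- centre(y); a <- centre(a); x <- centre(x)
  csum <- function(p, q) {
    if (is.matrix(p) || is.matrix(q)) colSums(p * q) else sum(p * q)
  }
  Sxy <- csum(x, y); Saa <- csum(a, a); Sax <- csum(a, x)
  Say <- csum(a, y); Sxx <- csum(x, x)
  den <- Sxx * Saa - Sax^2
  ok <- is.finite(den) & den > 1e-12
  b <- ifelse(ok, (Sxy * Saa - Sax * Say) / den, 0)
  list(b = b, ok = ok)
}

# z-score columns; zero-variance columns are flagged and left at zero
zscore_cols <- function(m) {
  mu <- colMeans(m)
  sd_ <- sqrt(colMeans(m^2) - mu^2) * sqrt(nrow(m) / (nrow(m) - 1))
  bad <- sd_ <= 0 | !is.finite(sd_)
  sd_[bad] <- 1
  list(z = sweep(sweep(m, 2, mu), 2, sd_, `/`), degenerate = bad)
}

#' Seed path-coefficient map (resting state)
#'
#' Estimates the lag-1 path coefficient between the seed series and every
#' in-mask voxel, in the requested direction, over the full (preprocessed)
#' resting series. For `seed_to_brain` the map holds the coefficient of the
#' lagged seed predicting each voxel; for `brain_to_seed`, the coefficient
#' of each lagged voxel predicting the seed. Constant (degenerate) voxels
#' receive 0 and are counted in the result.
#'
#' @param vol A preprocessed [vol4d()].
#' @param seed_series Seed time series (length `T`).
#' @param direction `"seed_to_brain"` or `"brain_to_seed"`.
#' @param lag Time lag in samples.
#' @param state State label stored in the map.
#' @return A `pc_map`.
#' @export
seed_pc_map <- function(vol, seed_series,
                        direction = c("seed_to_brain", "brain_to_seed"),
                        lag = 1, state = "rest") {
  stopifnot(inherits(vol, "vol4d"))
  direction <- match.arg(direction)
  nt <- n_vols(vol)
  if (length(seed_series) != nt) stop("seed series length must equal volume count")
  if (stats::sd(seed_series) == 0) stop("seed series is constant")
  sdim <- dim(vol$data)[1:3]
  inmask <- which(as.logical(vol$mask))
  m <- matrix(vol$data, prod(sdim), nt)
  V <- t(m[inmask, , drop = FALSE])            # T x Vmask
  zs <- zscore_cols(V)
  s <- as.numeric(scale(seed_series))
  idx <- (lag + 1):nt
  res <- if (direction == "seed_to_brain") {
    fwl_coefficient(y = zs$z[idx, , drop = FALSE],
                    a = zs$z[idx - lag, , drop = FALSE],
                    x = s[idx - lag])
  } else {
    fwl_coefficient(y = s[idx],
                    a = s[idx - lag],
                    x = zs$z[idx - lag, , drop = FALSE])
  }
  b <- res$b
  b[zs$degenerate] <- 0
  n_deg <- sum(zs$degenerate)
  if (n_deg > 0) message(n_deg, " degenerate voxel(s) set to 0")
  vals <- array(NA_real_, sdim)
  vals[inmask] <- b
  new_pc_map(vals, direction, state, vol$affine, vol$mask,
             n_degenerate = as.integer(n_deg))
}

#' Blockwise task path-coefficient map
#'
#' Estimates the task-state path coefficient using only the volumes of the
#' chosen condition (the 2-back blocks by default): within each block the
#' series are linearly detrended, mean-centred and (by default) scaled to
#' unit SD, the lag-1 path coefficient is computed per voxel, and the final
#' map is the unweighted mean across blocks. Blocks shorter than
#' `min_block_vols` are dropped with a warning.
#'
#' @param vol A preprocessed [vol4d()] task scan.
#' @param seed_series Seed series over the full task scan.
#' @param design The [generate_task_design()] design.
#' @param condition Condition defining the task state.
#' @param direction `"seed_to_brain"` or `"brain_to_seed"`.
#' @param lag Time lag in samples.
#' @param zscore Scale to unit SD within block (in addition to the
#'   mean-centring that is always applied).
#' @param min_block_vols Minimum usable volumes per block.
#' @return A `pc_map` with `n_blocks` set.
#' @export
blockwise_task_pc <- function(vol, seed_series, design, condition = "2-back",
                              direction = c("seed_to_brain", "brain_to_seed"),
                              lag = 1, zscore = TRUE, min_block_vols = 6) {
  stopifnot(inherits(vol, "vol4d"), inherits(design, "task_design"))
  direction <- match.arg(direction)
  nt <- n_vols(vol)
  if (length(seed_series) != nt) stop("seed series length must equal volume count")
  blocks <- condition_block_indices(design, vol$tr, nt, condition)
  usable <- Filter(function(ix) length(ix) >= min_block_vols, blocks)
  if (length(usable) < length(blocks)) {
    warning(length(blocks) - length(usable), " block(s) shorter than ",
            min_block_vols, " volumes dropped")
  }
  if (length(usable) == 0) stop("no usable ", condition, " blocks")

  sdim <- dim(vol$data)[1:3]
  inmask <- which(as.logical(vol$mask))
  m <- matrix(vol$data, prod(sdim), nt)

  acc <- numeric(length(inmask))
  deg_any <- logical(length(inmask))
  for (ix in usable) {
    Vb <- t(m[inmask, ix, drop = FALSE])       # Tb x V
    sb <- seed_series[ix]
    Vb <- detrend_block(Vb)
    sb <- as.numeric(detrend_block(matrix(sb)))
    if (zscore) {
      zs <- zscore_cols(Vb)
      Vb <- zs$z; deg <- zs$degenerate
      ssd <- stats::sd(sb)
      if (ssd > 0) sb <- sb / ssd
    } else {
      deg <- apply(Vb, 2, stats::sd) == 0
    }
    idx <- (lag + 1):nrow(Vb)
    res <- if (direction == "seed_to_brain") {
      fwl_coefficient(y = Vb[idx, , drop = FALSE],
                      a = Vb[idx - lag, , drop = FALSE],
                      x = sb[idx - lag])
    } else {
      fwl_coefficient(y = sb[idx], a = sb[idx - lag],
                      x = Vb[idx - lag, , drop = FALSE])
    }
    b <- res$b
    b[deg] <- 0
    deg_any <- deg_any | deg
    acc <- acc + b
  }
  vals <- array(NA_real_, sdim)
  vals[inmask] <- acc / length(usable)
  new_pc_map(vals, direction, "task", vol$affine, vol$mask,
             n_blocks = length(usable), n_degenerate = sum(deg_any))
}

# per-block volume indices (absolute) for a condition
condition_block_indices <- function(design, tr, nt, condition) {
  sv <- session_n_vols(design, tr)
  ns <- attr(design, "n_sessions")
  if (nt != sv * ns) stop("design covers ", sv * ns, " volumes but scan has ", nt)
  win <- condition_windows(design, condition)
  out <- list()
  for (r in seq_len(nrow(win))) {
    idx <- volumes_in_window(win$onset[r], win$duration[r], tr, sv) +
      (win$session[r] - 1) * sv
    out[[r]] <- idx
  }
  out
}

# remove a linear trend (with intercept) from each column
detrend_block <- function(m) {
  tt <- seq_len(nrow(m))
  qr.resid(qr(cbind(1, tt)), m)
}

#' Change-of-path-coefficient (CPC) map
#'
#' The central rest-to-task contrast: voxelwise task-state minus rest-state
#' path coefficient for one direction. A positive CPC means the directed
#' influence is larger during the task than at rest.
#'
#' @param pc_task,pc_rest `pc_map`s of the same direction on the same grid.
#' @return A `cpc_map`.
#' @export
cpc_map <- function(pc_task, pc_rest) {
  stopifnot(inherits(pc_task, "pc_map"), inherits(pc_rest, "pc_map"))
  if (pc_task$direction != pc_rest$direction) stop("direction mismatch")
  if (!identical(dim(pc_task$values), dim(pc_rest$values))) stop("grid mismatch")
  if (!isTRUE(all.equal(pc_task$affine, pc_rest$affine))) stop("affine mismatch")
  structure(list(values = pc_task$values - pc_rest$values,
                 direction = pc_task$direction,
                 affine = pc_task$affine, mask = pc_task$mask,
                 n_blocks = pc_task$n_blocks),
            class = "cpc_map")
}

#' @export
print.cpc_map <- function(x, ...) {
  cat(sprintf("<cpc_map> %s, %d voxels\n", x$direction, sum(x$mask)))
  invisible(x)
}

#' Functional-connectivity change map
#'
#' The undirected control analysis: per-voxel Pearson correlation with the
#' seed at rest (full series) and during the task (per condition block
#' after detrend/demean, averaged across blocks); the map is task minus
#' rest.
#'
#' @param vol_rest,vol_task Preprocessed [vol4d()]s.
#' @param seed_rest,seed_task Seed series for each state.
#' @param design Task design.
#' @param condition Task condition label.
#' @param min_block_vols Minimum usable volumes per block.
#' @return A `cpc_map`-like object with `direction = "fc"`.
#' @export
fc_change_map <- function(vol_rest, vol_task, seed_rest, seed_task, design,
                          condition = "2-back", min_block_vols = 6) {
  stopifnot(inherits(vol_rest, "vol4d"), inherits(vol_task, "vol4d"))
  sdim <- dim(vol_rest$data)[1:3]
  inmask <- which(as.logical(vol_rest$mask))

  corr_cols <- function(M, s) {
    Mc <- sweep(M, 2, colMeans(M))
    sc <- s - mean(s)
    den <- sqrt(colSums(Mc^2) * sum(sc^2))
    out <- ifelse(den > 0, colSums(Mc * sc) / den, 0)
    out
  }

  mr <- matrix(vol_rest$data, prod(sdim), n_vols(vol_rest))
  r_rest <- corr_cols(t(mr[inmask, , drop = FALSE]), seed_rest)

  nt <- n_vols(vol_task)
  blocks <- condition_block_indices(design, vol_task$tr, nt, condition)
  usable <- Filter(function(ix) length(ix) >= min_block_vols, blocks)
  if (!length(usable)) stop("no usable ", condition, " blocks")
  mt <- matrix(vol_task$data, prod(sdim), nt)
  acc <- numeric(length(inmask))
  for (ix in usable) {
    Vb <- detrend_block(t(mt[inmask, ix, drop = FALSE]))
    sb <- as.numeric(detrend_block(matrix(seed_task[ix])))
    acc <- acc + corr_cols(Vb, sb)
  }
  vals <- array(NA_real_, sdim)
  vals[inmask] <- acc / length(usable) - r_rest
  structure(list(values = vals, direction = "fc", affine = vol_rest$affine,
                 mask = vol_rest$mask, n_blocks = length(usable)),
            class = "cpc_map")
}
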