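#' Discard initial volumes
#'
#' Removes the first `n` volumes from a scan and its confound table
#' consistently (steady-state magnetisation discard; 5 volumes by default
#' in the resting chain).
#'
#' @param vol A [vol4d()].
#' @param confounds A matching [confound_set()].
#' @param n Number of leading volumes to drop; must be smaller than the run
#'   length.
#' @return List with shortened `vol` and `confounds`.
#' @export
discard_initial_volumes <- function(vol, confounds, n = 5) {
  stopifnot(inherits(vol, "vol4d"), inherits(confounds, "confound_set"))
  nt <- n_vols(vol)
  if (n_confound_rows(confounds) != nt) {
    stop("confound rows do not match volume count")
  }
  if (n < 0 || n != floor(n)) stop("n must be a non-negative integer")
  if (n >= nt) stop("cannot discard ", n, " of ", nt, " volumes")
  if (n == 0) return(list(vol = vol, confounds = confounds))
  keep <- (n + 1):nt
  v <- vol4d(vol$data[, , , keep, drop = FALSE], vol$affine, vol$tr, vol$mask)
  list(vol = v, confounds = subset_confounds(confounds, keep))
}

#' Scrub high-motion volumes by interpolation
#'
#' Timepoints whose framewise displacement exceeds `threshold` are replaced,
#' per voxel, by linear interpolation between the nearest unflagged
#' neighbours (nearest-neighbour continuation at the run edges). The series
#' length is unchanged — a linear-interpolation stand-in for repair-style
#' deweighting.
#'
#' @param vol A [vol4d()].
#' @param fd Framewise-displacement series (mm), one value per volume.
#' @param threshold Flagging threshold in mm (`fd > threshold`).
#' @return A [vol4d()] with flagged volumes replaced.
#' @export
scrub_interpolate <- function(vol, fd, threshold = 0.5) {
  stopifnot(inherits(vol, "vol4d"))
  nt <- n_vols(vol)
  if (length(fd) != nt) stop("fd length must equal volume count")
  if (threshold <= 0) stop("threshold must be positive")
  flagged <- which(fd > threshold)
  if (!length(flagged)) return(vol)
  good <- setdiff(seq_len(nt), flagged)
  if (!length(good)) stop("all timepoints flagged; cannot interpolate")

  v <- prod(dim(vol$data)[1:3])
  m <- matrix(vol$data, v, nt)
  for (t in flagged) {
    prev <- good[good < t]
    nxt <- good[good > t]
    if (!length(prev)) {
      m[, t] <- m[, nxt[1]]
    } else if (!length(nxt)) {
      m[, t] <- m[, prev[length(prev)]]
    } else {
      p <- prev[length(prev)]; q <- nxt[1]
      w <- (t - p) / (q - p)
      m[, t] <- (1 - w) * m[, p] + w * m[, q]
    }
  }
  vol4d(array(m, dim(vol$data)), vol$affine, vol$tr, vol$mask)
}

#' Spatial Gaussian smoothing
#'
#' Per-volume separable 3D Gaussian convolution with kernel
#' `sd = fwhm / (2 sqrt(2 ln 2))` per axis, specified in mm and converted
#' through the voxel size implied by the affine. Edge handling renormalises
#' the truncated kernel, so constants are preserved. Voxels outside the
#' mask are zeroed afterwards.
#'
#' @param vol A [vol4d()].
#' @param fwhm Full width at half maximum in mm; 0 is the identity.
#' @param apply_mask Zero voxels outside the mask after smoothing.
#' @return A smoothed [vol4d()].
#' @export
spatial_smooth <- function(vol, fwhm = 8, apply_mask = TRUE) {
  stopifnot(inherits(vol, "vol4d"))
  if (fwhm < 0) stop("fwhm must be non-negative")
  vs <- abs(diag(vol$affine)[1:3])
  if (any(vs <= 0)) stop("non-positive voxel size in affine")
  dat <- smooth_array(vol$data, fwhm, vs)
  if (apply_mask) {
    dat <- dat * as.numeric(vol$mask)   # recycles over the 4th dim
  }
  vol4d(dat, vol$affine, vol$tr, vol$mask)
}

# separable Gaussian smoothing of a 3D or 4D array; voxel sizes in mm.
# One compiled pass per axis with an edge-renormalised truncated kernel.
smooth_array <- function(dat, fwhm, voxel_size) {
  fwhm <- rep_len(fwhm, 3)
  if (all(fwhm == 0)) return(dat)
  voxel_size <- rep_len(voxel_size, 3)
  sd_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / voxel_size
  d <- dim(dat)
  out <- .gaussian_smooth_cpp(as.numeric(dat), as.integer(d),
                              as.numeric(sd_vox))
  array(out, d)
}

#' Temporal band-pass filter
#'
#' Ideal frequency-domain band-pass per voxel: Fourier bins with frequency
#' inside `[low, high]` Hz are retained, all others (including DC) are
#' zeroed, so the output is zero-mean per voxel.
#'
#' @param vol A [vol4d()].
#' @param low,high Passband edges in Hz; `0 <= low < high < ` Nyquist
#'   (`1 / (2 TR)`).
#' @return A filtered [vol4d()].
#' @export
temporal_bandpass <- function(vol, low = 0.01, high = 0.08) {
  stopifnot(inherits(vol, "vol4d"))
  nyq <- 1 / (2 * vol$tr)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high >= nyq) stop("high must be below the Nyquist frequency ", signif(nyq, 3), " Hz")
  nt <- n_vols(vol)
  v <- prod(dim(vol$data)[1:3])
  m <- matrix(vol$data, v, nt)
  f <- stats::mvfft(t(m))                      # nt x v, freq along rows
  freqs <- (seq_len(nt) - 1) / (nt * vol$tr)
  freqs <- pmin(freqs, 1 / vol$tr - freqs)     # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  f[!keep, ] <- 0
  out <- Re(stats::mvfft(f, inverse = TRUE)) / nt
  vol4d(array(t(out), dim(vol$data)), vol$affine, vol$tr, vol$mask)
}

#' Build HRF-convolved task regressors
#'
#' One column per condition label: a boxcar set to 1 inside the condition's
#' windows is convolved with the canonical HRF session by session (so no
#' response bleeds across a session boundary) and sampled at the volume
#' acquisition midpoints.
#'
#' @param design A [generate_task_design()] design.
#' @param tr Repetition time (s).
#' @param n_vols Total volumes across all sessions; must equal
#'   `session_n_vols(design, tr) * n_sessions`.
#' @param conditions Labels to build columns for.
#' @param hrf_fun HRF sampler, called as `hrf_fun(t_grid)`.
#' @param dt Fine-grid resolution of the convolution (s).
#' @return `n_vols x length(conditions)` matrix with named columns.
#' @export
build_task_regressors <- function(design, tr, n_vols,
                                  conditions = c("0-back", "1-back", "2-back"),
                                  hrf_fun = canonical_hrf, dt = 0.1) {
  stopifnot(inherits(design, "task_design"), tr > 0)
  sv <- session_n_vols(design, tr)
  ns <- attr(design, "n_sessions")
  if (n_vols != sv * ns) {
    stop("design covers ", sv * ns, " volumes but scan has ", n_vols)
  }
  if (!identical(hrf_fun, canonical_hrf)) {
    return(build_task_regressors_impl(design, tr, n_vols, conditions,
                                      hrf_fun, dt, sv, ns))
  }
  key <- list("taskreg", as.data.frame(design)[c("label", "onset", "duration",
                                                 "session")],
              tr, n_vols, conditions, dt)
  return(memo(key, build_task_regressors_impl(design, tr, n_vols, conditions,
                                              hrf_fun, dt, sv, ns)))
}

build_task_regressors_impl <- function(design, tr, n_vols, conditions,
                                       hrf_fun, dt, sv, ns) {
  dur <- attr(design, "session_duration")
  tgrid <- seq(0, max(dur, sv * tr) + 32, by = dt)
  h <- hrf_fun(tgrid)
  mids <- (seq_len(sv) - 0.5) * tr

  out <- matrix(0, n_vols, length(conditions),
                dimnames = list(NULL, conditions))
  for (ci in seq_along(conditions)) {
    for (s in seq_len(ns)) {
      w <- design[design$label == conditions[ci] & design$session == s, ]
      box <- numeric(length(tgrid))
      if (nrow(w)) {
        for (r in seq_len(nrow(w))) {
          box[tgrid >= w$onset[r] & tgrid < w$onset[r] + w$duration[r]] <- 1
        }
      }
      conv <- stats::convolve(box, rev(h), type = "open")[seq_along(tgrid)] * dt
      reg <- stats::approx(tgrid, conv, xout = mids, rule = 2)$y
      out[(s - 1) * sv + seq_len(sv), ci] <- reg
    }
  }
  out
}

#' Nuisance regression
#'
#' Per-voxel ordinary least-squares residualisation of the time series on
#' an intercept plus the supplied regressors. Residuals are orthogonal to
#' every regressor column.
#'
#' @param vol A [vol4d()].
#' @param regressors `T x p` numeric matrix (no intercept column needed).
#' @return A [vol4d()] of residuals.
#' @export
nuisance_regress <- function(vol, regressors) {
  stopifnot(inherits(vol, "vol4d"))
  nt <- n_vols(vol)
  X <- cbind(intercept = 1, as.matrix(regressors))
  if (nrow(X) != nt) stop("regressor rows must equal volume count")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("regressor matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  v <- prod(dim(vol$data)[1:3])
  m <- t(matrix(vol$data, v, nt))              # nt x v
  res <- qr.resid(qx, m)
  vol4d(array(t(res), dim(vol$data)), vol$affine, vol$tr, vol$mask)
}

#' Extract the mean seed time series
#'
#' Averages the series of all in-mask voxels whose centre lies within
#' `radius` mm of the seed centre. If no voxel centre falls inside the
#' sphere (radius below the voxel spacing), the voxel containing the centre
#' is used.
#'
#' @param vol A [vol4d()].
#' @param centre_mm Seed centre, mm (length 3). The default is the right
#'   anterior insula seed (33, 21, -3).
#' @param radius_mm Sphere radius in mm.
#' @return Numeric vector of length `T`.
#' @export
extract_seed_ts <- function(vol, centre_mm = c(33, 21, -3), radius_mm = 6) {
  stopifnot(inherits(vol, "vol4d"), radius_mm >= 0)
  idx <- seed_voxel_indices(vol, centre_mm, radius_mm)
  nt <- n_vols(vol)
  v <- prod(dim(vol$data)[1:3])
  m <- matrix(vol$data, v, nt)
  colMeans(m[idx, , drop = FALSE])
}

# linear indices of in-mask voxels in the seed sphere
seed_voxel_indices <- function(vol, centre_mm, radius_mm) {
  sdim <- dim(vol$data)[1:3]
  coords <- grid_mm_coords(vol$affine, sdim)
  d2 <- rowSums(sweep(coords, 2, centre_mm)^2)
  inside <- which(d2 <= radius_mm^2 & as.logical(vol$mask))
  if (!length(inside)) {
    ijk <- nearest_voxel(vol$affine, centre_mm)
    if (any(ijk < 1) || any(ijk > sdim)) stop("seed sphere does not intersect the grid")
    lin <- ijk[1] + (ijk[2] - 1) * sdim[1] + (ijk[3] - 1) * sdim[1] * sdim[2]
    if (!vol$mask[lin]) stop("seed sphere does not intersect the mask")
    inside <- lin
  }
  inside
}

#' Resting-state preprocessing chain
#'
#' Default chain: discard initial volumes, scrub by FD, smooth, band-pass,
#' then regress the nuisance set (6 motion parameters, global, WM and CSF
#' signals).
#'
#' @param vol A [vol4d()] resting scan.
#' @param confounds Matching [confound_set()].
#' @param n_discard Leading volumes to drop.
#' @param scrub_threshold FD threshold in mm (`NULL` disables scrubbing).
#' @param fwhm Smoothing kernel FWHM in mm.
#' @param band Passband in Hz, or `NULL` to skip filtering.
#' @return List with preprocessed `vol` and the trimmed `confounds`.
#' @export
preprocess_rest <- function(vol, confounds, n_discard = 5,
                            scrub_threshold = 0.5, fwhm = 8,
                            band = c(0.01, 0.08)) {
  d <- discard_initial_volumes(vol, confounds, n_discard)
  v <- d$vol; cf <- d$confounds
  if (!is.null(scrub_threshold)) v <- scrub_interpolate(v, cf$fd, scrub_threshold)
  if (fwhm > 0) v <- spatial_smooth(v, fwhm)
  if (!is.null(band)) v <- temporal_bandpass(v, band[1], band[2])
  X <- cbind(cf$motion, global = cf$global, wm = cf$wm, csf = cf$csf)
  v <- nuisance_regress(v, X)
  list(vol = v, confounds = cf)
}

#' Task preprocessing chain
#'
#' Scrub, smooth, then regress — session by session — the nuisance set
#' augmented with the HRF-convolved condition regressors. The band-pass of
#' the resting chain is replaced by the task-regressor augmentation; the
#' session-wise regression (including each session's own global signal)
#' implements state-specific global-signal removal.
#'
#' @param vol A [vol4d()] task scan (sessions concatenated).
#' @param confounds Matching [confound_set()].
#' @param design The [generate_task_design()] design.
#' @param scrub_threshold FD threshold in mm (`NULL` disables scrubbing).
#' @param fwhm Smoothing kernel FWHM in mm.
#' @param conditions Condition labels to model as task regressors.
#' @return List with preprocessed `vol` and `confounds`.
#' @export
preprocess_task <- function(vol, confounds, design, scrub_threshold = 0.5,
                            fwhm = 8,
                            conditions = c("0-back", "1-back", "2-back")) {
  stopifnot(inherits(vol, "vol4d"), inherits(confounds, "confound_set"),
            inherits(design, "task_design"))
  nt <- n_vols(vol)
  if (n_confound_rows(confounds) != nt) {
    stop("confound rows do not match volume count")
  }
  v <- vol
  if (!is.null(scrub_threshold)) v <- scrub_interpolate(v, confounds$fd, scrub_threshold)
  if (fwhm > 0) v <- spatial_smooth(v, fwhm)

  reg <- build_task_regressors(design, v$tr, nt, conditions)
  sv <- session_n_vols(design, v$tr)
  ns <- attr(design, "n_sessions")
  nvox <- prod(dim(v$data)[1:3])
  m <- matrix(v$data, nvox, nt)
  for (s in seq_len(ns)) {
    rows <- (s - 1) * sv + seq_len(sv)
    X <- cbind(1, confounds$motion[rows, ], confounds$global[rows],
               confounds$wm[rows], confounds$csf[rows],
               reg[rows, , drop = FALSE])
    keep <- apply(X, 2, function(col) stats::sd(col) > 0 | col[1] == 1)
    keep[1] <- TRUE
    qx <- qr(X[, keep, drop = FALSE])
    if (qx$rank < sum(keep)) stop("session ", s, ": rank-deficient nuisance matrix")
    m[, rows] <- t(qr.resid(qx, t(m[, rows, drop = FALSE])))
  }
  list(vol = vol4d(array(m, dim(v$data)), v$affine, v$tr, v$mask),
       confounds = confounds)
}
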