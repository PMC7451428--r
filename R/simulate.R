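#' Simulate the latent state-switching VAR(1) system
#'
#' Generates the latent node time series for one subject: a resting run in
#' which the lag-1 dynamics follow `A_rest` throughout, and a task run in
#' which a volume follows the task matrix whenever its acquisition midpoint
#' falls inside a window of `task_condition` (default the 2-back blocks) and
#' `A_rest` otherwise (instruction and gap periods included). Innovations
#' are Gaussian with the spec's per-node SDs; a burn-in is discarded so
#' both runs start from the stationary regime.
#'
#' @param spec A [network_spec()].
#' @param design A [generate_task_design()] design.
#' @param n_rest_vols Number of resting volumes to return.
#' @param tr Repetition time in seconds.
#' @param group `"SZ"` or `"HC"` — selects `A_task_SZ` / `A_task_HC` unless
#'   `A_task` is given.
#' @param A_task Optional explicit task matrix (overrides the group's).
#' @param task_condition Condition label defining the task state.
#' @param burn_in Discarded leading samples per run.
#' @param rng_seed Optional seed.
#' @return List: `rest` (`n_rest_vols x K` matrix), `task`
#'   (`n_task_vols x K`), `task_state` (logical per task volume), and
#'   `n_task_vols`.
#' @export
simulate_var_system <- function(spec, design, n_rest_vols = 240, tr = 2.5,
                                group = c("HC", "SZ"), A_task = NULL,
                                task_condition = "2-back", burn_in = 50,
                                rng_seed = NULL) {
  stopifnot(inherits(spec, "network_spec"), inherits(design, "task_design"))
  group <- match.arg(group)
  if (tr <= 0) stop("tr must be positive")
  A_task <- A_task %||% if (group == "SZ") spec$A_task_SZ else spec$A_task_HC
  for (A in list(spec$A_rest, A_task)) {
    if (spectral_radius(A) >= 1) stop("coefficient matrix is non-stationary")
  }
  k <- length(spec$node_ids)
  sv <- session_n_vols(design, tr)
  ns <- attr(design, "n_sessions")
  n_task <- sv * ns

  # per-volume state flags, session by session
  win <- condition_windows(design, task_condition)
  state <- logical(n_task)
  for (s in seq_len(ns)) {
    ws <- win[win$session == s, ]
    off <- (s - 1) * sv
    for (r in seq_len(nrow(ws))) {
      idx <- volumes_in_window(ws$onset[r], ws$duration[r], tr, sv)
      state[off + idx] <- TRUE
    }
  }

  with_seed(rng_seed, {
    rest <- var_run(list(spec$A_rest), rep(1L, n_rest_vols + burn_in),
                    spec$noise_sd, k)[-seq_len(burn_in), , drop = FALSE]
    st <- c(rep(1L, burn_in), ifelse(state, 2L, 1L))
    task <- var_run(list(spec$A_rest, A_task), st, spec$noise_sd,
                    k)[-seq_len(burn_in), , drop = FALSE]
    colnames(rest) <- colnames(task) <- spec$node_ids
    list(rest = rest, task = task, task_state = state, n_task_vols = n_task)
  })
}

# iterate x_t = A[[state_t]] x_{t-1} + e_t from x_0 = 0
var_run <- function(As, state_idx, noise_sd, k) {
  n <- length(state_idx)
  x <- matrix(0, n, k)
  e <- matrix(stats::rnorm(n * k), n, k) %*% diag(noise_sd, k)
  prev <- rep(0, k)
  for (t in seq_len(n)) {
    prev <- As[[state_idx[t]]] %*% prev + e[t, ]
    x[t, ] <- prev
  }
  x
}

#' Embed latent node series into a 4D volume
#'
#' Writes each node's time series into the grid as a Gaussian spatial
#' profile (peak 1 at the node centre, SD `spatial_sd` mm) around its mm
#' position, adds i.i.d. Gaussian voxel noise, and attaches the affine and
#' mask. Node positions must fall inside the grid.
#'
#' @param latent `T x K` matrix of node series (columns named by node).
#' @param positions `K x 3` node centres in mm.
#' @param sdim Spatial grid dimensions (length 3).
#' @param affine 4x4 voxel-to-mm affine.
#' @param tr Repetition time (s).
#' @param spatial_sd Gaussian profile SD in mm.
#' @param voxel_noise_sd I.i.d. voxel noise SD.
#' @param mask Optional 3D logical mask (default ellipsoid).
#' @param common_ts Optional length-`T` series added uniformly to every
#'   voxel (global artefact / tissue nuisance).
#' @param rng_seed Optional seed for the voxel noise.
#' @return A [vol4d()].
#' @export
embed_in_volume <- function(latent, positions, sdim, affine, tr,
                            spatial_sd = 4, voxel_noise_sd = 1,
                            mask = NULL, common_ts = NULL, rng_seed = NULL) {
  latent <- as.matrix(latent)
  positions <- rbind_coords(positions)
  k <- ncol(latent)
  if (nrow(positions) != k) stop("positions must have one row per latent column")
  nt <- nrow(latent)
  v <- prod(sdim)
  node_names <- colnames(latent) %||% paste0("node", seq_len(k))

  vox <- mm_to_vox(affine, positions)
  out_lo <- vox < -0.5
  out_hi <- sweep(vox, 2, sdim - 0.5, `>`)
  bad <- which(rowSums(out_lo | out_hi) > 0)
  if (length(bad)) {
    stop("node position outside grid: ", paste(node_names[bad], collapse = ", "))
  }

  prof <- memo(list("profiles", affine, sdim, positions, spatial_sd), {
    coords <- grid_mm_coords(affine, sdim)    # v x 3
    p <- matrix(0, v, k)
    for (j in seq_len(k)) {
      d2 <- rowSums(sweep(coords, 2, positions[j, ])^2)
      p[, j] <- exp(-d2 / (2 * spatial_sd^2))
      p[p[, j] < 1e-6, j] <- 0
    }
    p
  })

  if (!is.null(common_ts)) {
    stopifnot(length(common_ts) == nt)
    latent <- cbind(latent, common_ts)        # flat unit profile column
    prof <- cbind(prof, 1)
  }
  dat <- tcrossprod(prof, latent)             # v x nt
  with_seed(rng_seed, {
    if (voxel_noise_sd > 0) {
      dat <- dat + matrix(stats::rnorm(v * nt, 0, voxel_noise_sd), v, nt)
    }
    vol4d(array(dat, c(sdim, nt)), affine, tr, mask %||% ellipsoid_mask(sdim))
  })
}

# nearest array index (1-based) of an mm position
nearest_voxel <- function(affine, mm) {
  as.integer(round(mm_to_vox(affine, mm)) + 1)
}
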