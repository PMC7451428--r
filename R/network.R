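#' Directed network specification for the cohort simulator
#'
#' Defines the latent node set (a seed plus K targets), their spatial
#' positions in mm, and the lag-1 coefficient matrices governing directed
#' influences in each state: `A_rest` (shared), and task-state matrices
#' `A_task_SZ` / `A_task_HC` per group. Rows are receivers: the latent
#' process is `x_t = A x_{t-1} + e_t`, so entry `A[i, j]` is the influence
#' of node `j` at lag 1 on node `i`.
#'
#' @param node_ids Character vector of node labels; the first node is the
#'   seed.
#' @param positions Numeric matrix `K+1 x 3` of node centres in mm.
#' @param A_rest,A_task_SZ,A_task_HC Square lag-1 coefficient matrices of
#'   size `K+1`; every matrix must be stationary (spectral radius < 1) with
#'   diagonal entries in `[0, 1)`.
#' @param noise_sd Innovation standard deviation per node (recycled).
#' @return A `network_spec` object.
#' @export
network_spec <- function(node_ids, positions, A_rest, A_task_SZ, A_task_HC,
                         noise_sd = 1) {
  k <- length(node_ids)
  positions <- rbind_coords(positions)
  if (nrow(positions) != k) stop("positions must have one row per node")
  for (nm in c("A_rest", "A_task_SZ", "A_task_HC")) {
    A <- get(nm)
    if (!is.matrix(A) || !all(dim(A) == k)) {
      stop(nm, " must be a square matrix of size ", k)
    }
    if (any(diag(A) < 0 | diag(A) >= 1)) stop(nm, " diagonal entries must be in [0, 1)")
    if (spectral_radius(A) >= 1) stop(nm, " is non-stationary (spectral radius >= 1)")
  }
  noise_sd <- rep_len(noise_sd, k)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  structure(list(node_ids = node_ids, positions = positions,
                 A_rest = A_rest, A_task_SZ = A_task_SZ, A_task_HC = A_task_HC,
                 noise_sd = noise_sd),
            class = "network_spec")
}

spectral_radius <- function(A) max(Mod(eigen(A, only.values = TRUE)$values))

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("<network_spec> %d nodes (seed: %s)\n", length(x$node_ids),
              x$node_ids[1]))
  invisible(x)
}

#' Default three-node network for a given grid
#'
#' Places the seed ("rAI") and two synthetic target nodes well inside the
#' grid and at least `min_sep` mm apart. The rest matrix carries modest
#' autocorrelation on every node and a weak baseline seed-to-target edge;
#' the task matrices are copies whose planted edges the cohort generator
#' overwrites per subject.
#'
#' @param sdim Spatial grid dimensions.
#' @param voxel_size Voxel size in mm.
#' @param origin Affine origin (mm of voxel 0,0,0); defaults to centring the
#'   grid on the seed position `seed_mm`.
#' @param seed_mm Seed centre in mm (right anterior insula by default).
#' @param auto Diagonal (autoregressive) coefficient shared by all nodes.
#' @param b_rest Baseline rest-state seed-to-target coefficient.
#' @param noise_sd Innovation SD.
#' @param min_sep Minimum node separation in mm (checked).
#' @return List with elements `spec` (a [network_spec()]) and `affine`.
#' @export
default_network_spec <- function(sdim = c(24, 28, 24), voxel_size = 3,
                                 origin = NULL, seed_mm = c(33, 21, -3),
                                 auto = 0.3, b_rest = 0.05, noise_sd = 1,
                                 min_sep = 12) {
  if (is.null(origin)) origin <- seed_mm - voxel_size * floor(sdim / 2)
  affine <- make_affine(voxel_size, origin)
  half <- voxel_size * sdim / 2
  ctr <- origin + half
  # targets: offset from grid centre along distinct axes, inside the mask
  t1 <- ctr + c(-0.55, 0.45, 0.35) * half
  t2 <- ctr + c(0.45, -0.55, -0.4) * half
  pos <- rbind(seed_mm, t1, t2)
  d <- as.matrix(stats::dist(pos))
  if (min(d[upper.tri(d)]) < min_sep) {
    stop("default node placement violates the minimum separation; supply positions")
  }
  A <- diag(rep(auto, 3))
  A[2, 1] <- b_rest   # seed -> target 1
  A[3, 1] <- b_rest   # seed -> target 2
  spec <- network_spec(c("rAI", "target1", "target2"), pos,
                       A_rest = A, A_task_SZ = A, A_task_HC = A,
                       noise_sd = noise_sd)
  list(spec = spec, affine = affine)
}
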