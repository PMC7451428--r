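#' Per-timepoint nuisance regressor set
#'
#' Bundles the six rigid-body motion parameters (translations in mm,
#' rotations in rad), the global / white-matter / CSF mean signals, and the
#' framewise-displacement series derived from the motion parameters.
#'
#' @param motion Numeric matrix `T x 6`: columns
#'   `trans_x, trans_y, trans_z` (mm) then `rot_x, rot_y, rot_z` (rad).
#' @param global,wm,csf Numeric vectors of length `T` (mean tissue signals).
#' @return A `confound_set`: list with `motion`, `global`, `wm`, `csf`,
#'   `fd` (mm; `fd[1] = 0`) and `mean_fd` (mean over timepoints 2..T).
#' @export
confound_set <- function(motion, global = NULL, wm = NULL, csf = NULL) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  n <- nrow(motion)
  global <- global %||% rep(0, n)
  wm <- wm %||% rep(0, n)
  csf <- csf %||% rep(0, n)
  if (length(global) != n || length(wm) != n || length(csf) != n) {
    stop("confound column lengths must equal the motion series length")
  }
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  fd <- compute_fd(motion)
  structure(list(motion = motion, global = as.numeric(global),
                 wm = as.numeric(wm), csf = as.numeric(csf),
                 fd = fd$fd, mean_fd = fd$mean_fd),
            class = "confound_set")
}

#' @export
print.confound_set <- function(x, ...) {
  cat(sprintf("<confound_set> %d timepoints, mean FD %.3f mm\n",
              nrow(x$motion), x$mean_fd))
  invisible(x)
}

n_confound_rows <- function(cf) nrow(cf$motion)

# Subset a confound set to timepoint indices (recomputes FD on the subset).
subset_confounds <- function(cf, idx) {
  confound_set(cf$motion[idx, , drop = FALSE], cf$global[idx],
               cf$wm[idx], cf$csf[idx])
}

#' Framewise displacement from motion parameters
#'
#' Power's scalar framewise displacement: the sum of absolute backward
#' differences of the three translations plus the three rotations converted
#' to arc length on a 50-mm sphere,
#' `fd_t = sum |d trans| + 50 * sum |d rot|`. The first timepoint has no
#' predecessor and is assigned 0; `mean_fd` averages timepoints 2..T.
#'
#' @param motion `T x 6` matrix (translations mm, rotations rad), `T >= 2`.
#' @param rotation_radius_mm Sphere radius converting radians to mm.
#' @return List with `fd` (length `T`) and `mean_fd`.
#' @export
compute_fd <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 timepoints")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  list(fd = fd, mean_fd = mean(fd[-1]))
}

#' Subject-level exclusion screen
#'
#' Applies the study inclusion rules: exclude when any absolute translation
#' exceeds 3.0 mm, any absolute rotation exceeds 3.0 degrees, or the task
#' hit rate falls below 30 percent. Comparisons at the motion boundary are
#' strict ("exceeding"), and the hit-rate rule is strict ("< 30").
#'
#' @param record A list or one-row data frame with at least `hit_rate`
#'   (percent); may be `NULL`/missing for rest-only screening.
#' @param motion `T x 6` motion matrix (translations mm, rotations rad).
#' @param max_translation_mm,max_rotation_deg,min_hit_rate Rule thresholds.
#' @param require_hit_rate Set `TRUE` when screening task data; a missing
#'   hit rate is then an error instead of a pass-through.
#' @return List with `keep` (logical) and `reason` (`NA` when kept; one of
#'   `"motion"`, `"performance"`).
#' @export
exclusion_screen <- function(record, motion,
                             max_translation_mm = 3.0,
                             max_rotation_deg = 3.0,
                             min_hit_rate = 30,
                             require_hit_rate = FALSE) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion must have 6 columns")
  max_t <- max(abs(motion[, 1:3]))
  max_r_deg <- max(abs(motion[, 4:6])) * 180 / pi
  if (max_t > max_translation_mm || max_r_deg > max_rotation_deg) {
    return(list(keep = FALSE, reason = "motion"))
  }
  hr <- record$hit_rate
  if (is.null(hr) || length(hr) == 0 || is.na(hr[1])) {
    if (require_hit_rate) stop("hit_rate missing from record for task screening")
    return(list(keep = TRUE, reason = NA_character_))
  }
  if (hr[1] < min_hit_rate) return(list(keep = FALSE, reason = "performance"))
  list(keep = TRUE, reason = NA_character_)
}

#' Write / read confounds as TSV
#' @param cf A `confound_set`.
#' @param path File path.
#' @return `read_confounds` returns a `confound_set`.
#' @export
write_confounds <- function(cf, path) {
  df <- data.frame(cf$motion, global = cf$global, wm = cf$wm, csf = cf$csf)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_confounds
#' @export
read_confounds <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
            "global", "wm", "csf")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("confound file missing columns: ",
                            paste(missing, collapse = ", "))
  confound_set(as.matrix(df[, need[1:6]]), df$global, df$wm, df$csf)
}

# Random-walk motion trace calibrated so the expected mean FD matches
# `target_mean_fd`; occasional spikes exercise scrubbing.
simulate_motion <- function(n, target_mean_fd = 0.15, spike_prob = 0.01,
                            spike_mm = 0.8, rotation_radius_mm = 50) {
  # E|N(0,s)| = s*sqrt(2/pi); FD sums 3 translation + 3 scaled rotation terms
  s_t <- target_mean_fd / (6 * sqrt(2 / pi))
  s_r <- s_t / rotation_radius_mm
  steps <- cbind(matrix(stats::rnorm(3 * n, 0, s_t), n, 3),
                 matrix(stats::rnorm(3 * n, 0, s_r), n, 3))
  spikes <- stats::runif(n) < spike_prob
  if (any(spikes)) {
    steps[spikes, 1] <- steps[spikes, 1] +
      sample(c(-1, 1), sum(spikes), TRUE) * spike_mm
  }
  steps[1, ] <- 0
  apply(steps, 2, cumsum)
}
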