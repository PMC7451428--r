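#' Plot an axial slice of a statistic map
#'
#' Heat-map of one axial (z) slice of a `pc_map`, `cpc_map` or
#' `group_t_map`, in mm coordinates, with out-of-mask voxels blank.
#'
#' @param map A `pc_map`, `cpc_map` or `group_t_map`.
#' @param z_mm Slice position in mm (nearest grid slice is used); default
#'   is the slice with the largest absolute value.
#' @return A ggplot object.
#' @export
plot_map_slice <- function(map, z_mm = NULL) {
  vals <- if (inherits(map, "group_t_map")) map$t else map$values
  mask <- map$mask
  affine <- map$affine
  sdim <- dim(vals)
  v <- vals
  v[!mask] <- NA
  if (is.null(z_mm)) {
    k <- which.max(apply(abs(v), 3, max, na.rm = TRUE))
  } else {
    k <- round(mm_to_vox(affine, c(0, 0, z_mm))[3]) + 1
    k <- min(max(k, 1), sdim[3])
  }
  sl <- v[, , k]
  xs <- vox_to_mm(affine, cbind(seq_len(sdim[1]) - 1, 0, 0))[, 1]
  ys <- vox_to_mm(affine, cbind(0, seq_len(sdim[2]) - 1, 0))[, 2]
  df <- expand.grid(x = xs, y = ys)
  df$value <- as.vector(sl)
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("axial slice z = %g mm",
                                  vox_to_mm(affine, c(0, 0, k - 1))[3])) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a cluster-level association
#'
#' Cluster-mean CPC against a behavioural or clinical score, coloured by
#' group, as used to display hit-rate and symptom correlations.
#'
#' @param cluster_means Per-subject cluster-mean CPCs.
#' @param participants Participants tibble.
#' @param variable Score column to plot against.
#' @return A ggplot object.
#' @export
plot_association <- function(cluster_means, participants,
                             variable = "hit_rate") {
  df <- tibble::tibble(cpc = as.numeric(cluster_means),
                       score = participants[[variable]],
                       group = participants$group)
  df <- df[!is.na(df$score), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cpc, y = .data$score,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "cluster-mean CPC", y = variable) +
    ggplot2::theme_minimal()
}

#' Null maximum-cluster-extent distribution
#'
#' Histogram of the Monte-Carlo null distribution with the derived extent
#' threshold marked.
#'
#' @param null_max_extent Integer vector from
#'   [alphasim_extent_threshold()].
#' @param extent_threshold The derived threshold.
#' @return A ggplot object.
#' @export
plot_null_extent <- function(null_max_extent, extent_threshold) {
  df <- tibble::tibble(extent = null_max_extent)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$extent)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60") +
    ggplot2::geom_vline(xintercept = extent_threshold, colour = "firebrick",
                        linetype = 2) +
    ggplot2::labs(x = "max cluster extent (voxels)", y = "simulations") +
    ggplot2::theme_minimal()
}
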