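#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cluster table
#'
#' One row per corrected cluster with its peak statistics and group
#' summaries; the `voxels` and `cluster_means` list-columns are dropped.
#'
#' @param x A `cluster_table` from [extract_clusters()] (possibly
#'   annotated by [run_pipeline()]).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cluster_table <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x),
                -dplyr::any_of(c("voxels", "cluster_means")))
}

#' Tidy a pipeline run
#'
#' Stacks the corrected cluster tables of all directions.
#'
#' @param x A `restshift_run`.
#' @param ... Unused.
#' @return A tibble with a `direction` column.
#' @export
tidy.restshift_run <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$clusters), function(d) {
    cl <- tidy.cluster_table(x$clusters[[d]])
    if (nrow(cl)) dplyr::mutate(cl, direction = d, .before = 1) else NULL
  }))
}

#' One-line run summary
#'
#' @param x A `restshift_run`.
#' @param ... Unused.
#' @return A one-row tibble: subject counts, cluster counts per direction,
#'   extent thresholds and mean smoothness.
#' @export
glance.restshift_run <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$provenance$n_subjects,
    n_sz = x$provenance$n_sz, n_hc = x$provenance$n_hc,
    n_clusters = sum(vapply(x$clusters, nrow, 0L)),
    extent_threshold = paste(unlist(x$extent_threshold), collapse = "/"),
    mean_fwhm_mm = mean(unlist(x$smoothness_mm)),
    seed = x$provenance$rng_seed)
}
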