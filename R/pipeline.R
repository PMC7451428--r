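#' Pipeline run configuration
#'
#' Bundles every option of an end-to-end run with defaults equal to the
#' analysis defaults: lag-1 path coefficients, 2-back task state, seed
#' sphere of 6 mm at (33, 21, -3), voxel p 0.01 with cluster-level alpha
#' 0.05, and 26-neighbour connectivity.
#'
#' @param cohort Either a [cohort_config()] (simulation) or a directory
#'   path holding a written dataset (see [load_dataset()]).
#' @param seed_mm,seed_radius_mm Seed sphere specification.
#' @param lag GCM lag in samples.
#' @param condition Task condition used for the task state.
#' @param zscore_blocks Z-score within task blocks (in addition to
#'   detrend/demean).
#' @param directions Map directions to analyse.
#' @param voxel_p,alpha Voxel-level and cluster-level thresholds.
#' @param n_iter Monte-Carlo iterations for the extent threshold.
#' @param connectivity Cluster connectivity (6/18/26).
#' @param covariates Covariate columns for the group design.
#' @param n_discard,scrub_threshold,fwhm,band Preprocessing options.
#' @param compute_fc Also compute the functional-connectivity change maps.
#' @param activation_control Compute per-subject activation beta maps and
#'   the activation-adjusted group test for each cluster.
#' @param extent_threshold_fun Optional function `(mask, fwhm)` returning a
#'   precomputed `alphasim_extent_threshold()` result (e.g. a memoised
#'   wrapper when many runs share one mask); `NULL` computes it in-run.
#' @param rng_seed Master seed for all randomness in the run.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = demo_cohort_config(),
                       seed_mm = NULL, seed_radius_mm = 6,
                       lag = 1, condition = "2-back", zscore_blocks = TRUE,
                       directions = c("seed_to_brain", "brain_to_seed"),
                       voxel_p = 0.01, alpha = 0.05, n_iter = 1000,
                       connectivity = 26,
                       covariates = c("age", "gender", "mean_fd_rest",
                                      "mean_fd_task"),
                       n_discard = 5, scrub_threshold = 0.5, fwhm = 8,
                       band = c(0.01, 0.08), compute_fc = FALSE,
                       activation_control = TRUE,
                       extent_threshold_fun = NULL,
                       rng_seed = 1) {
  if (is.null(seed_mm) && inherits(cohort, "cohort_config")) {
    seed_mm <- cohort$spec$positions[1, ]
  }
  seed_mm <- seed_mm %||% c(33, 21, -3)
  cfg <- list(cohort = cohort, seed_mm = seed_mm,
              seed_radius_mm = seed_radius_mm, lag = lag,
              condition = condition, zscore_blocks = zscore_blocks,
              directions = directions, voxel_p = voxel_p, alpha = alpha,
              n_iter = n_iter, connectivity = connectivity,
              covariates = covariates, n_discard = n_discard,
              scrub_threshold = scrub_threshold, fwhm = fwhm, band = band,
              compute_fc = compute_fc,
              activation_control = activation_control,
              extent_threshold_fun = extent_threshold_fun,
              rng_seed = rng_seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full rest-to-task connectivity pipeline
#'
#' Simulates (or loads) the cohort, preprocesses every subject's resting
#' and task runs, estimates seed path-coefficient maps in both directions
#' and both states, forms CPC maps, performs the covariate-adjusted group
#' comparison with Monte-Carlo cluster-extent correction, runs per-group
#' one-sample tests and the activation-confound control for each surviving
#' cluster, and computes the cluster-level association battery. Rerunning
#' with an identical configuration reproduces all outputs.
#'
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, maps, tables, the log
#'   and a provenance record are written there.
#' @param progress Print stage messages.
#' @return A `restshift_run` object (list): `participants`, `clusters` and
#'   `associations` per direction, `group_t`, `extent_threshold`,
#'   `smoothness_mm`, `cpc_maps`, `ground_truth` (when simulated), and
#'   `provenance`.
#' @export
run_pipeline <- function(config, output_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (progress) message(...)
  t0 <- Sys.time()

  simulated <- inherits(config$cohort, "cohort_config")
  if (simulated) {
    ccfg <- config$cohort
    base <- generate_cohort(ccfg, config$rng_seed, volumes = FALSE)
    participants <- base$participants
    design <- base$design
    ground_truth <- base$ground_truth
    par <- cohort_params(ccfg, config$rng_seed)
    n <- nrow(participants)
    get_subject <- function(i) generate_subject(ccfg, par, design, i,
                                                config$rng_seed)
  } else {
    ds <- load_dataset(config$cohort)
    participants <- ds$participants
    design <- ds$design
    ground_truth <- NULL
    n <- nrow(participants)
    get_subject <- function(i) ds$subjects[[i]]
  }

  dirs <- config$directions
  cpc <- stats::setNames(vector("list", length(dirs)), dirs)
  for (d in dirs) cpc[[d]] <- vector("list", n)
  fc <- if (config$compute_fc) vector("list", n) else NULL
  act_beta_maps <- vector("list", n)
  seed_vox <- NULL
  warn_counts <- c(dropped_blocks = 0L, degenerate_voxels = 0L)

  for (i in seq_len(n)) {
    say("subject ", i, "/", n)
    sub <- get_subject(i)
    pr <- preprocess_rest(sub$rest, sub$confounds_rest,
                          n_discard = config$n_discard,
                          scrub_threshold = config$scrub_threshold,
                          fwhm = config$fwhm, band = config$band)
    # smoothed (not task-regressed) copy for activation betas
    vt_s <- sub$task
    if (!is.null(config$scrub_threshold)) {
      vt_s <- scrub_interpolate(vt_s, sub$confounds_task$fd,
                                config$scrub_threshold)
    }
    if (config$fwhm > 0) vt_s <- spatial_smooth(vt_s, config$fwhm)
    pt <- preprocess_task(vt_s, sub$confounds_task, design,
                          scrub_threshold = NULL, fwhm = 0)
    if (is.null(seed_vox)) {
      seed_vox <- seed_voxel_indices(pr$vol, config$seed_mm,
                                     config$seed_radius_mm)
    }
    seed_rest <- extract_seed_ts(pr$vol, config$seed_mm,
                                 config$seed_radius_mm)
    seed_task <- extract_seed_ts(pt$vol, config$seed_mm,
                                 config$seed_radius_mm)
    for (d in dirs) {
      pc_r <- seed_pc_map(pr$vol, seed_rest, d, lag = config$lag)
      pc_t <- suppressMessages(blockwise_task_pc(
        pt$vol, seed_task, design, condition = config$condition,
        direction = d, lag = config$lag, zscore = config$zscore_blocks))
      warn_counts["degenerate_voxels"] <-
        warn_counts[["degenerate_voxels"]] + pc_r$n_degenerate + pc_t$n_degenerate
      cpc[[d]][[i]] <- cpc_map(pc_t, pc_r)
    }
    if (config$compute_fc) {
      fc[[i]] <- fc_change_map(pr$vol, pt$vol, seed_rest, seed_task, design,
                               condition = config$condition)
    }
    if (config$activation_control) {
      act_beta_maps[[i]] <- activation_beta_map(vt_s, sub$confounds_task,
                                                design)
    }
  }

  X <- group_design(participants, config$covariates)
  n_sz <- sum(participants$group == "SZ")
  n_hc <- sum(participants$group == "HC")
  mask <- cpc[[1]][[1]]$mask
  affine <- cpc[[1]][[1]]$affine
  voxel_size <- abs(diag(affine)[1:3])

  group_t <- list(); clusters <- list(); associations <- list()
  smoothness <- list(); extent <- list()
  for (d in dirs) {
    say("group inference: ", d)
    gt <- voxelwise_group_t(cpc[[d]], X)
    fw <- estimate_smoothness(gt$residuals, mask, voxel_size)
    al <- if (!is.null(config$extent_threshold_fun)) {
      config$extent_threshold_fun(mask, fw)
    } else {
      alphasim_extent_threshold(mask, fw, config$voxel_p, config$alpha,
                                n_iter = config$n_iter,
                                connectivity = config$connectivity,
                                voxel_size = voxel_size,
                                rng_seed = derive_seed(config$rng_seed,
                                                       "alphasim"))
    }
    cl <- extract_clusters(gt, config$voxel_p, al$extent_threshold,
                           config$connectivity,
                           null_max_extent = al$null_max_extent)
    cl <- annotate_clusters(cl, cpc[[d]], participants, X,
                            act_beta_maps, seed_vox, n_sz, n_hc)
    group_t[[d]] <- gt
    smoothness[[d]] <- fw
    extent[[d]] <- al$extent_threshold
    clusters[[d]] <- cl
    associations[[d]] <- if (nrow(cl) > 0) {
      cm <- as.data.frame(stats::setNames(cl$cluster_means, cl$label))
      association_battery(cm, participants)
    } else NULL
  }

  prov <- list(config_hash = rlang::hash(strip_env(config)),
               rng_seed = config$rng_seed,
               n_subjects = n, n_sz = n_sz, n_hc = n_hc,
               simulated = simulated,
               warnings = as.list(warn_counts),
               version = as.character(utils::packageVersion("restshift")),
               elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  run <- structure(list(participants = participants, design = design,
                        cpc_maps = cpc, fc_maps = fc, group_t = group_t,
                        smoothness_mm = smoothness,
                        extent_threshold = extent, clusters = clusters,
                        associations = associations,
                        ground_truth = ground_truth, config = config,
                        provenance = prov),
                   class = "restshift_run")
  if (!is.null(output_dir)) write_run(run, output_dir)
  run
}

strip_env <- function(x) {
  # drop environments (closures) so hashing is stable
  rapply(x, function(e) NULL, classes = "function", how = "replace")
}

# voxelwise activation beta map for the 2-back regressor
activation_beta_map <- function(vol, confounds, design, condition = "2-back") {
  nt <- n_vols(vol)
  v <- prod(dim(vol$data)[1:3])
  reg <- build_task_regressors(design, vol$tr, nt)
  sv <- session_n_vols(design, vol$tr)
  ns <- attr(design, "n_sessions")
  sess <- factor(rep(seq_len(ns), each = sv))
  X <- cbind(stats::model.matrix(~sess), confounds$motion,
             global = confounds$global, wm = confounds$wm,
             csf = confounds$csf, reg)
  qx <- qr(X)
  Y <- t(matrix(vol$data, v, nt))
  co <- qr.coef(qx, Y)
  array(co[match(condition, colnames(X)), ], dim(vol$data)[1:3])
}

annotate_clusters <- function(cl, cpc_maps, participants, X, act_maps,
                              seed_vox, n_sz, n_hc) {
  if (nrow(cl) == 0) {
    cl$cluster_means <- list()
    return(cl)
  }
  is_sz <- participants$group == "SZ"
  res <- lapply(seq_len(nrow(cl)), function(r) {
    vox <- cl$voxels[[r]]
    means <- cluster_mean_cpc(cpc_maps, vox)
    fit_t <- cluster_group_t(means, X)
    os_sz <- one_sample_cluster_t(means[is_sz])
    os_hc <- one_sample_cluster_t(means[!is_sz])
    ac <- if (!is.null(act_maps[[1]])) {
      act_seed <- vapply(act_maps, function(a) mean(a[seed_vox]), numeric(1))
      act_cl <- vapply(act_maps, function(a) mean(a[vox]), numeric(1))
      activation_control(means, cbind(seed = act_seed, cluster = act_cl), X)
    } else tibble::tibble(statistic = NA_real_, p = NA_real_)
    tibble::tibble(
      cluster_means = list(means),
      mean_sz = mean(means[is_sz]), sd_sz = stats::sd(means[is_sz]),
      mean_hc = mean(means[!is_sz]), sd_hc = stats::sd(means[!is_sz]),
      t_cluster = fit_t$statistic, df_cluster = fit_t$df,
      p_cluster_t = fit_t$p,
      d_cluster = cohens_d_from_t(fit_t$statistic, n_sz, n_hc),
      t_onesample_sz = os_sz$statistic, p_onesample_sz = os_sz$p,
      t_onesample_hc = os_hc$statistic, p_onesample_hc = os_hc$p,
      t_activation_ctrl = ac$statistic, p_activation_ctrl = ac$p)
  })
  dplyr::bind_cols(cl, dplyr::bind_rows(res))
}

# covariate-adjusted two-sample t on cluster means
cluster_group_t <- function(values, X) {
  qx <- qr(X)
  df <- length(values) - ncol(X)
  fit <- stats::lm.fit(X, values)
  XtXinv <- chol2inv(qr.R(qx))
  j <- match("group", colnames(X))
  se <- sqrt(sum(fit$residuals^2) / df * XtXinv[j, j])
  tt <- unname(fit$coefficients[j] / se)
  tibble::tibble(statistic = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' Write a completed run to a directory
#'
#' Writes group t-maps (NIfTI), cluster tables, association tables and the
#' null extent distribution (TSV), plus `provenance.json` and a plain-text
#' log.
#'
#' @param run A `restshift_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(run$group_t)) {
    gt <- run$group_t[[d]]
    tvol <- vol4d(array(ifelse(is.finite(gt$t), gt$t, 0),
                        c(dim(gt$t), 1)), gt$affine, 1, gt$mask)
    write_vol4d(tvol, file.path(dir, paste0("tmap_", d, ".nii")),
                write_mask = (d == names(run$group_t)[1]))
    cl <- run$clusters[[d]]
    readr::write_tsv(dplyr::select(tibble::as_tibble(cl),
                                   -dplyr::any_of(c("voxels", "cluster_means"))),
                     file.path(dir, paste0("clusters_", d, ".tsv")))
    if (!is.null(run$associations[[d]])) {
      readr::write_tsv(run$associations[[d]],
                       file.path(dir, paste0("associations_", d, ".tsv")))
    }
  }
  readr::write_tsv(run$participants, file.path(dir, "participants.tsv"))
  jsonlite::write_json(run$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(report(run), file.path(dir, "report.txt"))
  invisible(dir)
}

#' Human-readable run report
#'
#' Formats each direction's corrected clusters in the conventional table
#' layout — area label, per-group mean (SD) of cluster CPC, peak T, p,
#' Cohen's d, peak MNI coordinates and cluster size K — followed by the
#' association results.
#'
#' @param run A `restshift_run`.
#' @return Character vector of report lines.
#' @export
report <- function(run) {
  stopifnot(inherits(run, "restshift_run"))
  ln <- c(sprintf("restshift run — %d subjects (%d SZ / %d HC)",
                  run$provenance$n_subjects, run$provenance$n_sz,
                  run$provenance$n_hc),
          sprintf("config hash %s, seed %s", run$provenance$config_hash,
                  run$provenance$rng_seed))
  for (d in names(run$clusters)) {
    cl <- run$clusters[[d]]
    ln <- c(ln, "", sprintf("Direction: %s (extent threshold %d voxels, FWHM %.1f mm)",
                            d, run$extent_threshold[[d]],
                            mean(run$smoothness_mm[[d]])))
    if (nrow(cl) == 0) {
      ln <- c(ln, "  no suprathreshold clusters")
      next
    }
    ln <- c(ln, sprintf("  %-10s %-16s %-16s %7s %9s %6s %-14s %5s",
                        "Area", "SZ mean (SD)", "HC mean (SD)", "T", "p",
                        "d", "MNI", "K"))
    for (r in seq_len(nrow(cl))) {
      ln <- c(ln, sprintf("  %-10s %-16s %-16s %7.2f %9.2g %6.2f %-14s %5d",
                          cl$label[r],
                          sprintf("%.3f (%.2f)", cl$mean_sz[r], cl$sd_sz[r]),
                          sprintf("%.3f (%.2f)", cl$mean_hc[r], cl$sd_hc[r]),
                          cl$peak_t[r], cl$cluster_p[r], cl$d_cluster[r],
                          sprintf("%g %g %g", cl$peak_x[r], cl$peak_y[r],
                                  cl$peak_z[r]),
                          cl$extent[r]))
    }
    assoc <- run$associations[[d]]
    if (!is.null(assoc)) {
      sig <- assoc[assoc$significant, ]
      ln <- c(ln, sprintf("  associations: %d tests, %d significant",
                          nrow(assoc), nrow(sig)))
      for (r in seq_len(nrow(sig))) {
        ln <- c(ln, sprintf("    %s ~ %s [%s, %s]: estimate %.3f, p %.4f",
                            sig$cluster[r], sig$variable[r], sig$group[r],
                            sig$method[r], sig$estimate[r], sig$p[r]))
      }
    }
  }
  ln
}

#' @export
print.restshift_run <- function(x, ...) {
  cat(report(x), sep = "\n")
  invisible(x)
}

#' Write a generated cohort to a dataset directory
#'
#' Layout: `participants.tsv`, `task_design.tsv`, `ground_truth.json`
#' (when present) and per subject `<id>_rest.nii` / `<id>_task.nii` with
#' `<id>_confounds_rest.tsv` / `<id>_confounds_task.tsv`.
#'
#' @param cohort Result of [generate_cohort()] (with volumes).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(!is.null(cohort$subjects))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(cohort$participants, file.path(dir, "participants.tsv"))
  write_task_design(cohort$design, file.path(dir, "task_design.tsv"))
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    gt$subjects <- as.data.frame(gt$subjects)
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  first <- TRUE
  for (s in cohort$subjects) {
    write_vol4d(s$rest, file.path(dir, paste0(s$id, "_rest.nii")),
                write_mask = first)
    write_vol4d(s$task, file.path(dir, paste0(s$id, "_task.nii")),
                write_mask = FALSE)
    write_confounds(s$confounds_rest,
                    file.path(dir, paste0(s$id, "_confounds_rest.tsv")))
    write_confounds(s$confounds_task,
                    file.path(dir, paste0(s$id, "_confounds_task.tsv")))
    first <- FALSE
  }
  invisible(dir)
}

#' Load a dataset directory
#'
#' Reads the layout written by [write_cohort()], validating presence of
#' required files and consistency of TR, grid and affine across subjects.
#'
#' @param dir Dataset directory.
#' @return List with `subjects`, `participants`, `design`, and
#'   `ground_truth` (`NULL` when absent).
#' @export
load_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("dataset directory not found: ", dir)
  ppath <- file.path(dir, "participants.tsv")
  if (!file.exists(ppath)) stop("missing participants.tsv")
  participants <- tibble::as_tibble(utils::read.delim(ppath))
  if (!"group" %in% names(participants)) {
    stop("participants table missing required column: group")
  }
  dpath <- file.path(dir, "task_design.tsv")
  if (!file.exists(dpath)) stop("missing task_design.tsv")
  design <- read_task_design(dpath)
  gpath <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gpath)) jsonlite::read_json(gpath) else NULL

  # shared mask from the first subject's rest companion file
  mask <- NULL
  ref <- NULL
  subjects <- lapply(seq_len(nrow(participants)), function(i) {
    id <- participants$id[i]
    paths <- file.path(dir, paste0(id, c("_rest.nii", "_task.nii",
                                         "_confounds_rest.tsv",
                                         "_confounds_task.tsv")))
    missing <- paths[!file.exists(paths)]
    if (length(missing)) stop("subject ", id, ": missing file(s) ",
                              paste(basename(missing), collapse = ", "))
    rest <- read_vol4d(paths[1])
    task <- read_vol4d(paths[2])
    if (is.null(mask)) {
      mask <<- rest$mask
      ref <<- rest
    } else {
      if (!isTRUE(all.equal(rest$tr, ref$tr, tolerance = 1e-6))) {
        stop("subject ", id, ": TR mismatch")
      }
      if (!isTRUE(all.equal(rest$affine, ref$affine, tolerance = 1e-4))) {
        stop("subject ", id, ": affine mismatch")
      }
      if (!identical(dim(rest$data)[1:3], dim(ref$data)[1:3])) {
        stop("subject ", id, ": grid mismatch")
      }
    }
    rest$mask <- mask
    task$mask <- mask
    list(id = id, group = participants$group[i], rest = rest, task = task,
         confounds_rest = read_confounds(paths[3]),
         confounds_task = read_confounds(paths[4]),
         record = participants[i, ])
  })
  list(subjects = subjects, participants = participants, design = design,
       ground_truth = ground_truth)
}
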