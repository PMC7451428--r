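#' Configuration for the synthetic two-group cohort
#'
#' Assembles every knob of the cohort generator with defaults emulating the
#' study conditions: 29 patients (SZ) and 31 controls (HC); a 10-minute
#' resting run of 240 volumes at TR 2.5 s; two task sessions of seven 110-s
#' n-back blocks; a seed node plus two targets embedded in a
#' 24 x 28 x 24-voxel grid at 3 mm with 4-mm Gaussian node profiles; and a
#' planted rest-to-task change of the seed-to-target1 path coefficient in
#' the SZ group only.
#'
#' The planted group effect `group_cpc_effect_d` is specified on the scale
#' of the *measured* voxel CPC: the generator converts it to a raw
#' task-edge shift via
#' `delta = d * sqrt((g * between_sd)^2 + est_sd^2) / g`, where `g`
#' (`estimator_attenuation`) is the end-to-end slope of measured CPC on
#' planted CPC and `est_sd` (`estimator_sd`) the per-subject sampling SD of
#' the measured CPC. Both constants ship as defaults obtained from the
#' package's own calibration simulation ([calibrate_cpc_estimator()]) at
#' the default acquisition geometry (they fold in blockwise small-sample
#' shrinkage, band-pass-limited resting degrees of freedom, smoothing and
#' voxel noise); re-run the calibration if you change the temporal layout,
#' smoothing, noise level or seed geometry materially. The behaviour
#' coupling `behaviour_coupling_r` is the within-group correlation between
#' each subject's *true* planted CPC and the hit rate.
#'
#' @param n_sz,n_hc Group sizes.
#' @param sdim Spatial grid dimensions.
#' @param voxel_size Voxel size (mm).
#' @param tr Repetition time (s).
#' @param n_rest_acquired Acquired resting volumes (before discarding).
#' @param n_discard Leading volumes the preprocessing chain removes.
#' @param n_blocks_per_session,n_sessions Task layout.
#' @param network Optional list(spec, affine) as from
#'   [default_network_spec()]; built for the grid when `NULL`.
#' @param planted_edges List of `c(from, to)` node-name pairs whose
#'   task-state coefficient differs between groups.
#' @param group_cpc_effect_d Standardised SZ-minus-HC difference in measured
#'   CPC at the planted edges (0 = null cohort).
#' @param between_subject_sd SD of true task-edge weights across subjects.
#' @param estimator_attenuation,estimator_sd Calibration constants of the
#'   end-to-end CPC estimator (slope of measured on planted CPC, and
#'   per-subject estimator SD); see [calibrate_cpc_estimator()].
#' @param behaviour_coupling_r Within-group correlation between true planted
#'   CPC (first planted edge) and hit rate; `|r| < 1`.
#' @param symptom_coupling_r As above for psychomotor poverty (SZ only).
#' @param activation List: `nodes` receiving HRF-convolved task activation
#'   and `amplitude` named by condition.
#' @param spatial_sd Node profile SD (mm).
#' @param voxel_noise_sd I.i.d. voxel noise SD.
#' @param global_drift_sd,tissue_sd Amplitudes of the injected global
#'   low-frequency drift and WM/CSF nuisance series.
#' @param motion_artifact Amplitude of the FD-locked global artefact.
#' @param mean_fd Named means (`sz`, `hc`) of the per-subject target mean
#'   FD (mm); subjects scatter around these.
#' @param hit_rate_mean,hit_rate_sd Named per-group hit-rate moments
#'   (percent).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_sz = 29, n_hc = 31,
                          sdim = c(24, 28, 24), voxel_size = 3,
                          tr = 2.5, n_rest_acquired = 240, n_discard = 5,
                          n_blocks_per_session = 7, n_sessions = 2,
                          network = NULL,
                          planted_edges = list(c("rAI", "target1")),
                          group_cpc_effect_d = 1.2,
                          between_subject_sd = 0.2,
                          estimator_attenuation = 0.73,
                          estimator_sd = 0.146,
                          behaviour_coupling_r = 0.5,
                          symptom_coupling_r = 0.4,
                          activation = list(nodes = c("rAI", "target1"),
                                            amplitude = c("0-back" = 0.4,
                                                          "1-back" = 0.7,
                                                          "2-back" = 1.0)),
                          spatial_sd = 4, voxel_noise_sd = 1,
                          global_drift_sd = 0.3, tissue_sd = 0.2,
                          motion_artifact = 0.5,
                          mean_fd = c(sz = 0.17, hc = 0.14),
                          hit_rate_mean = c(sz = 73.7, hc = 78.5),
                          hit_rate_sd = c(sz = 7.5, hc = 5.0)) {
  if (abs(behaviour_coupling_r) >= 1) stop("behaviour_coupling_r must satisfy |r| < 1")
  if (abs(symptom_coupling_r) >= 1) stop("symptom_coupling_r must satisfy |r| < 1")
  if (between_subject_sd < 0) stop("between_subject_sd must be non-negative")
  if (!is_count(n_sz) || !is_count(n_hc)) stop("group sizes must be positive integers")
  network <- network %||% default_network_spec(sdim, voxel_size)
  stopifnot(inherits(network$spec, "network_spec"))
  cfg <- list(n_sz = n_sz, n_hc = n_hc, sdim = sdim, voxel_size = voxel_size,
              tr = tr, n_rest_acquired = n_rest_acquired, n_discard = n_discard,
              n_blocks_per_session = n_blocks_per_session,
              n_sessions = n_sessions,
              spec = network$spec, affine = network$affine,
              mask = ellipsoid_mask(sdim),
              planted_edges = planted_edges,
              group_cpc_effect_d = group_cpc_effect_d,
              between_subject_sd = between_subject_sd,
              estimator_attenuation = estimator_attenuation,
              estimator_sd = estimator_sd,
              behaviour_coupling_r = behaviour_coupling_r,
              symptom_coupling_r = symptom_coupling_r,
              activation = activation,
              spatial_sd = spatial_sd, voxel_noise_sd = voxel_noise_sd,
              global_drift_sd = global_drift_sd, tissue_sd = tissue_sd,
              motion_artifact = motion_artifact,
              mean_fd = mean_fd, hit_rate_mean = hit_rate_mean,
              hit_rate_sd = hit_rate_sd)
  class(cfg) <- "cohort_config"
  cfg
}

#' Small demonstration-scale cohort configuration
#'
#' 12 + 12 subjects on a 16 x 18 x 16 grid — the desk-scale configuration
#' used for end-to-end recovery checks. All statistical parameters equal
#' the full defaults.
#'
#' @param n_sz,n_hc Group sizes.
#' @param sdim Spatial grid dimensions.
#' @param ... Further overrides forwarded to [cohort_config()].
#' @export
demo_cohort_config <- function(n_sz = 12, n_hc = 12, sdim = c(16, 18, 16),
                               ...) {
  cohort_config(n_sz = n_sz, n_hc = n_hc, sdim = sdim, ...)
}

#' First-order SD of the CPC estimator
#'
#' Approximates the sampling SD of the change-of-path-coefficient estimate
#' for one subject from the run geometry: the rest path coefficient is
#' estimated from `T_rest` retained volumes (OLS with intercept, lagged
#' target and lagged seed), the task coefficient from `n_blocks` blocks of
#' `vols_per_block` volumes each, averaged. A quick sanity figure; it
#' ignores band-pass-limited resting degrees of freedom, blockwise
#' detrending and voxel noise, all of which inflate the realised SD —
#' use [calibrate_cpc_estimator()] for the calibrated value.
#'
#' @param t_rest Retained resting volumes.
#' @param vols_per_block Volumes per task block.
#' @param n_blocks Number of task blocks.
#' @return Approximate SD (unitless, z-scored coefficient scale).
#' @export
cpc_estimation_sd <- function(t_rest = 235, vols_per_block = 12, n_blocks = 14) {
  se2_rest <- 1 / max(t_rest - 4, 1)
  se2_task <- 1 / max(vols_per_block - 4, 1) / n_blocks
  sqrt(se2_rest + se2_task)
}

#' Calibrate the end-to-end CPC estimator
#'
#' Measures, by simulation through the full per-subject pipeline
#' (generation, preprocessing, seed extraction, path-coefficient maps),
#' the linear relation between the CPC measured at the planted target
#' voxel and the planted true CPC: the regression slope is the estimator's
#' total attenuation `g` (blockwise small-sample shrinkage, band-pass,
#' smoothing, voxel noise and seed-sphere averaging combined) and the
#' residual SD its per-subject sampling noise. [cohort_config()] uses the
#' resulting constants to plant effect sizes on the observed scale.
#'
#' @param config A [cohort_config()]; its statistical defaults are used but
#'   group effect and couplings are irrelevant here.
#' @param n_subjects Pilot subjects per cohort.
#' @param n_cohorts Pilot cohorts (different parameter draws).
#' @param rng_seed Seed of the calibration simulation.
#' @return List with `attenuation`, `estimator_sd`, `n`.
#' @export
calibrate_cpc_estimator <- function(config = demo_cohort_config(),
                                    n_subjects = 24, n_cohorts = 3,
                                    rng_seed = 1) {
  tv <- nearest_voxel(config$affine, config$spec$positions[2, ])
  sdim <- config$sdim
  lin <- tv[1] + (tv[2] - 1) * sdim[1] + (tv[3] - 1) * sdim[1] * sdim[2]
  obs <- numeric(0); tru <- numeric(0)
  for (cseed in seq_len(n_cohorts)) {
    seed_c <- derive_seed(rng_seed, "noise") + cseed
    coh <- generate_cohort(config, seed_c, volumes = FALSE)
    par <- cohort_params(config, seed_c)
    design <- coh$design
    for (i in seq_len(min(n_subjects, nrow(coh$participants)))) {
      sub <- generate_subject(config, par, design, i, seed_c)
      pr <- preprocess_rest(sub$rest, sub$confounds_rest,
                            n_discard = config$n_discard)
      vt <- spatial_smooth(scrub_interpolate(sub$task, sub$confounds_task$fd,
                                             0.5), 8)
      pt <- preprocess_task(vt, sub$confounds_task, design,
                            scrub_threshold = NULL, fwhm = 0)
      sr <- extract_seed_ts(pr$vol, config$spec$positions[1, ])
      st <- extract_seed_ts(pt$vol, config$spec$positions[1, ])
      pcr <- seed_pc_map(pr$vol, sr, "seed_to_brain")
      pct <- suppressMessages(
        blockwise_task_pc(pt$vol, st, design, direction = "seed_to_brain"))
      obs <- c(obs, pct$values[lin] - pcr$values[lin])
      tru <- c(tru, coh$ground_truth$subjects$true_cpc[i])
    }
  }
  fit <- stats::lm(obs ~ tru)
  list(attenuation = unname(stats::coef(fit)[2]),
       estimator_sd = stats::sd(stats::resid(fit)),
       n = length(obs))
}

#' Generate a synthetic two-group cohort
#'
#' Draws subject records, planted edge weights, behaviour and symptom
#' scores, motion traces and 4D volumes for every subject. The two groups
#' share `A_rest`; they differ only in the task-state coefficients of the
#' configured `planted_edges`. The returned `ground_truth` records every
#' realized edge weight, true CPC and coupling used during generation.
#'
#' Identical `(config, rng_seed)` pairs reproduce the cohort bit-for-bit;
#' each subject's volumes are additionally reproducible in isolation via
#' [generate_subject()].
#'
#' @param config A [cohort_config()].
#' @param rng_seed Integer master seed.
#' @param volumes Set `FALSE` to skip volume generation (records, design and
#'   ground truth only) — useful when streaming subjects with
#'   [generate_subject()].
#' @return List with `subjects` (list of per-subject bundles: `id`, `group`,
#'   `rest`, `task` ([vol4d()]s), `confounds_rest`, `confounds_task`,
#'   `record`), `participants` (tibble), `design`, `ground_truth`, and
#'   `config`.
#' @export
generate_cohort <- function(config, rng_seed = 1, volumes = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  design <- generate_task_design(config$n_blocks_per_session,
                                 config$n_sessions,
                                 rng_seed = derive_seed(rng_seed, "design"))
  par <- cohort_params(config, rng_seed)
  subjects <- NULL
  if (volumes) {
    subjects <- lapply(seq_len(nrow(par$participants)), function(i) {
      generate_subject(config, par, design, i, rng_seed)
    })
  }
  list(subjects = subjects, participants = par$participants,
       design = design, ground_truth = par$ground_truth, config = config)
}

# Subject-level draws: records, edge weights, behaviour, motion traces.
cohort_params <- function(config, rng_seed) {
  n <- config$n_sz + config$n_hc
  group <- c(rep("SZ", config$n_sz), rep("HC", config$n_hc))
  g <- config$estimator_attenuation
  est_sd <- config$estimator_sd
  delta <- config$group_cpc_effect_d *
    sqrt((g * config$between_subject_sd)^2 + est_sd^2) / g

  with_seed(derive_seed(rng_seed, "behaviour"), {
    age <- ifelse(group == "SZ", stats::rnorm(n, 33.2, 9.2),
                  stats::rnorm(n, 33.8, 9.2))
    age <- pmin(pmax(age, 18), 65)
    gender <- ifelse(stats::runif(n) < ifelse(group == "SZ", 5 / 29, 9 / 31),
                     "F", "M")
    handed <- ifelse(stats::runif(n) < ifelse(group == "SZ", 5 / 29, 3 / 31),
                     "L", "R")
    fd_mu <- ifelse(group == "SZ", config$mean_fd[["sz"]], config$mean_fd[["hc"]])
    fd_rest_target <- pmax(stats::rnorm(n, fd_mu, 0.04), 0.05)
    fd_task_target <- pmax(stats::rnorm(n, fd_mu + 0.01, 0.04), 0.05)

    # planted task-edge weights; groups differ by `delta` on each edge
    edges <- config$planted_edges
    spec <- config$spec
    b_task <- matrix(NA_real_, n, max(length(edges), 1))
    b_rest <- numeric(max(length(edges), 1))
    if (length(edges)) {
      for (e in seq_along(edges)) {
        fr <- match(edges[[e]][1], spec$node_ids)
        to <- match(edges[[e]][2], spec$node_ids)
        if (is.na(fr) || is.na(to)) {
          stop("planted edge names unknown node: ",
               paste(edges[[e]], collapse = " -> "))
        }
        b_rest[e] <- spec$A_rest[to, fr]
        mu <- b_rest[e] + ifelse(group == "SZ", delta, 0)
        b_task[, e] <- stats::rnorm(n, mu, config$between_subject_sd)
      }
    }
    true_cpc <- if (length(edges)) b_task[, 1] - b_rest[1] else rep(0, n)

    # behaviour coupled to the true CPC of the first planted edge
    r_b <- config$behaviour_coupling_r
    z <- if (length(edges) && config$between_subject_sd > 0) {
      grp_mu <- stats::ave(b_task[, 1], group)
      (b_task[, 1] - grp_mu) / config$between_subject_sd
    } else stats::rnorm(n)
    hr_mu <- ifelse(group == "SZ", config$hit_rate_mean[["sz"]],
                    config$hit_rate_mean[["hc"]])
    hr_sd <- ifelse(group == "SZ", config$hit_rate_sd[["sz"]],
                    config$hit_rate_sd[["hc"]])
    hit_rate <- hr_mu + hr_sd * (r_b * z + sqrt(1 - r_b^2) * stats::rnorm(n))
    hit_rate <- pmin(pmax(hit_rate, 0), 100)

    r_s <- config$symptom_coupling_r
    pmp <- 5 + 2.5 * (r_s * z + sqrt(1 - r_s^2) * stats::rnorm(n))
    symptoms <- tibble::tibble(
      psychomotor_poverty = pmax(pmp, 0),
      disorganization = pmax(stats::rnorm(n, 3, 2), 0),
      reality_distortion = pmax(stats::rnorm(n, 3, 2), 0),
      sspi_total = pmax(stats::rnorm(n, 20, 8), 0),
      sofas = pmin(pmax(stats::rnorm(n, 45, 12), 0), 100),
      dose_ddd = pmax(stats::rnorm(n, 1.5, 1), 0.1),
      lifetime_exposure = stats::rlnorm(n, log(2500), 1.2))
    symptoms[group == "HC", ] <- NA

    motions_rest <- lapply(seq_len(n), function(i) {
      with_seed(subject_seed(rng_seed, i, 1L),
                simulate_motion(config$n_rest_acquired, fd_rest_target[i]))
    })
    nt <- task_total_vols(config)
    motions_task <- lapply(seq_len(n), function(i) {
      with_seed(subject_seed(rng_seed, i, 2L),
                simulate_motion(nt, fd_task_target[i]))
    })

    participants <- tibble::tibble(
      id = sprintf("sub-%03d", seq_len(n)), group = group,
      age = age, gender = gender, handedness = handed,
      mean_fd_rest = vapply(motions_rest, function(m) compute_fd(m)$mean_fd, 0),
      mean_fd_task = vapply(motions_task, function(m) compute_fd(m)$mean_fd, 0),
      hit_rate = hit_rate) |>
      dplyr::bind_cols(symptoms)

    gt_subjects <- tibble::tibble(
      id = participants$id, group = group, true_cpc = true_cpc)
    if (length(edges)) {
      for (e in seq_along(edges)) {
        lab <- paste(edges[[e]], collapse = "->")
        gt_subjects[[paste0("b_task_", lab)]] <- b_task[, e]
        gt_subjects[[paste0("b_rest_", lab)]] <- b_rest[e]
      }
    }
    ground_truth <- list(
      subjects = gt_subjects,
      edges = config$planted_edges,
      planted_effect_d = config$group_cpc_effect_d,
      task_edge_delta = delta,
      estimator_attenuation = g,
      estimator_sd = est_sd,
      couplings = list(hit_rate = config$behaviour_coupling_r,
                       psychomotor_poverty = config$symptom_coupling_r))

    list(participants = participants, b_task = b_task,
         motions_rest = motions_rest, motions_task = motions_task,
         ground_truth = ground_truth)
  })
}

task_total_vols <- function(config) {
  block_span <- 3 * 30 + 2 * 10
  as.integer(ceiling(config$n_blocks_per_session * block_span / config$tr)) *
    config$n_sessions
}

subject_seed <- function(master, i, stage) {
  ((as.double(master) * 131 + i * 7919 + stage * 104729) %%
     (.Machine$integer.max - 1)) + 1
}

#' Generate one subject's volumes and confounds
#'
#' Deterministic per `(config, rng_seed, i)`; used by [generate_cohort()]
#' and for streaming large cohorts one subject at a time.
#'
#' @param config A [cohort_config()].
#' @param par Cohort-level parameter draws; pass `NULL` to re-derive them
#'   from `(config, rng_seed)` (always identical), or reuse the draws
#'   across subjects when streaming to avoid recomputation.
#' @param design The cohort task design; `NULL` re-derives it.
#' @param i Subject index.
#' @param rng_seed Master seed of the cohort.
#' @return Per-subject bundle (see [generate_cohort()]).
#' @export
generate_subject <- function(config, par = NULL, design = NULL, i, rng_seed) {
  par <- par %||% cohort_params(config, rng_seed)
  design <- design %||% generate_task_design(
    config$n_blocks_per_session, config$n_sessions,
    rng_seed = derive_seed(rng_seed, "design"))
  rec <- par$participants[i, ]
  spec <- config$spec
  A_task <- if (rec$group == "SZ") spec$A_task_SZ else spec$A_task_HC
  edges <- config$planted_edges
  if (length(edges)) {
    for (e in seq_along(edges)) {
      fr <- match(edges[[e]][1], spec$node_ids)
      to <- match(edges[[e]][2], spec$node_ids)
      A_task[to, fr] <- par$b_task[i, e]
    }
  }
  if (spectral_radius(A_task) >= 1) {
    stop("subject ", rec$id, ": planted task matrix is non-stationary")
  }

  sim <- simulate_var_system(spec, design,
                             n_rest_vols = config$n_rest_acquired,
                             tr = config$tr, A_task = A_task,
                             rng_seed = subject_seed(rng_seed, i, 3L))

  # HRF-convolved task activation added to configured nodes
  task <- sim$task
  act_nodes <- intersect(config$activation$nodes %||% character(0),
                         spec$node_ids)
  if (length(act_nodes)) {
    sv <- session_n_vols(design, config$tr)
    reg <- build_task_regressors(design, config$tr, nrow(task))
    amp <- config$activation$amplitude
    keep <- intersect(names(amp), colnames(reg))
    if (length(keep)) {
      act <- as.numeric(reg[, keep, drop = FALSE] %*% amp[keep])
      for (nd in act_nodes) task[, nd] <- task[, nd] + act
    }
  }

  mot_r <- par$motions_rest[[i]]
  mot_t <- par$motions_task[[i]]
  v <- prod(config$sdim)

  build_scan <- function(latent, motion, stage) {
    nt <- nrow(latent)
    with_seed(subject_seed(rng_seed, i, stage), {
      drift <- config$global_drift_sd * ar1_series(nt, 0.97)
      wm <- config$tissue_sd * ar1_series(nt, 0.8)
      csf <- config$tissue_sd * ar1_series(nt, 0.8)
      fd <- compute_fd(motion)$fd
      art <- config$motion_artifact * (fd - mean(fd))
      common <- drift + wm + csf + art
      vol <- embed_in_volume(latent, spec$positions, config$sdim,
                             config$affine, config$tr,
                             spatial_sd = config$spatial_sd,
                             voxel_noise_sd = config$voxel_noise_sd,
                             mask = config$mask, common_ts = common,
                             rng_seed = subject_seed(rng_seed, i, stage + 10L))
      glob <- global_series(vol)
      list(vol = vol, cf = confound_set(motion, glob, wm, csf))
    })
  }

  rest <- build_scan(sim$rest, mot_r, 20L)
  taskb <- build_scan(task, mot_t, 30L)
  list(id = rec$id, group = rec$group,
       rest = rest$vol, task = taskb$vol,
       confounds_rest = rest$cf, confounds_task = taskb$cf,
       record = rec)
}

ar1_series <- function(n, phi) {
  as.numeric(stats::filter(stats::rnorm(n, 0, sqrt(1 - phi^2)), phi,
                           method = "recursive"))
}

global_series <- function(vol) {
  v <- prod(dim(vol$data)[1:3])
  m <- matrix(vol$data, v, dim(vol$data)[4])
  colMeans(m[as.logical(vol$mask), , drop = FALSE])
}
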