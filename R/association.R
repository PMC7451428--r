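#' Correlation with optional covariate adjustment
#'
#' Pearson or Spearman correlation between two vectors, optionally partial
#' with respect to covariates. Spearman is computed as Pearson on average
#' ranks (covariates are ranked too in the partial case); partial
#' correlation correlates the OLS residuals of `x` and `y` on the
#' covariates. The p value uses the t approximation
#' `t = r sqrt(df) / sqrt(1 - r^2)` with `df = n - 2 - #covariates`,
#' two-sided.
#'
#' @param x,y Numeric vectors (no missing values; apply pairwise deletion
#'   upstream).
#' @param method `"pearson"` or `"spearman"`.
#' @param covariates Optional numeric vector/matrix of covariates.
#' @return One-row tibble: `method`, `r`, `n`, `df`, `p`, `covariates`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      covariates = NULL) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  if (anyNA(x) || anyNA(y)) stop("missing values; apply pairwise deletion upstream")
  n <- length(x)
  k <- if (is.null(covariates)) 0 else ncol(as.matrix(covariates))
  if (n < 4 + k) stop("need at least ", 4 + k, " observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  cov_names <- if (k > 0) {
    paste(colnames(as.matrix(covariates)) %||% paste0("c", seq_len(k)),
          collapse = ",")
  } else ""

  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
    if (k > 0) covariates <- apply(as.matrix(covariates), 2, rank)
  }
  if (k > 0) {
    Z <- cbind(1, as.matrix(covariates))
    qz <- qr(Z)
    x <- qr.resid(qz, x)
    y <- qr.resid(qz, y)
  }
  r <- stats::cor(x, y)
  df <- n - 2 - k
  tt <- r * sqrt(df) / sqrt(1 - r^2)
  tibble::tibble(method = if (k > 0) paste0("partial-", method) else method,
                 r = r, n = n, df = df,
                 p = 2 * stats::pt(-abs(tt), df),
                 covariates = cov_names)
}

#' Compare two independent correlations (Fisher r-to-Z)
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`; the default
#' one-tailed p is the upper-tail normal probability (testing `r1 > r2`).
#'
#' @param r1,n1 First correlation and its sample size.
#' @param r2,n2 Second correlation and its sample size.
#' @param tail `"greater"` (r1 > r2), `"less"`, or `"two.sided"`.
#' @return One-row tibble: `z`, `p`, `tail`.
#' @export
fisher_r_to_z_compare <- function(r1, n1, r2, n2,
                                  tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be below 1")
  if (n1 < 4 || n2 < 4) stop("need n >= 4 in both samples")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(tail,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  tibble::tibble(z = z, p = p, tail = tail)
}

#' Pearson chi-square for a 2x2 table
#'
#' Without continuity correction (the form that reproduces standard
#' demographic-table statistics), df = 1.
#'
#' @param tab 2x2 matrix of counts.
#' @return One-row tibble: `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("all margins must be positive")
  }
  ct <- stats::chisq.test(tab, correct = FALSE)
  tibble::tibble(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value)
}

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance two-sample t with `df = n1 + n2 - 2`, computed from
#' group means, SDs and sizes (for comparing groups from published summary
#' rows).
#'
#' @param mean1,sd1,n1 First group summary.
#' @param mean2,sd2,n2 Second group summary.
#' @return One-row tibble: `statistic`, `df`, `p`, `d`.
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive")
  if (n1 < 2 || n2 < 2) stop("ns must be at least 2")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  tt <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  tibble::tibble(statistic = tt, df = df,
                 p = 2 * stats::pt(-abs(tt), df),
                 d = (mean1 - mean2) / sp)
}

#' Cluster-level behaviour, symptom and medication associations
#'
#' Runs the configured association tests on per-subject cluster-mean CPCs:
#' hit rate by Spearman within each group, symptom dimension scores by
#' Spearman within patients, SOFAS and SSPI total by Pearson within
#' patients, and antipsychotic dose / lifetime exposure by Spearman within
#' patients. Hypothesised tests use a two-tailed threshold of 0.025,
#' exploratory tests 0.05. For the hit rate, the group-wise correlations
#' are additionally compared by a one-tailed Fisher r-to-Z test
#' (HC greater than SZ by default).
#'
#' @param cluster_means Data frame or named list: one numeric column of
#'   per-subject cluster-mean CPCs per cluster, rows aligned with
#'   `participants`.
#' @param participants Participants tibble (columns `group`, `hit_rate`,
#'   symptom scores, `dose_ddd`, `lifetime_exposure`).
#' @param hypothesised Character vector of variables tested at the
#'   hypothesis threshold.
#' @param threshold_hypothesised,threshold_exploratory Two-tailed p
#'   thresholds.
#' @param fisher_tail Tail for the group-comparison of hit-rate
#'   correlations (`"greater"` tests HC > SZ).
#' @return Tidy tibble: `cluster`, `variable`, `group`, `method`,
#'   `estimate`, `n`, `df`, `p`, `threshold`, `significant`.
#' @export
association_battery <- function(cluster_means, participants,
                                hypothesised = "psychomotor_poverty",
                                threshold_hypothesised = 0.025,
                                threshold_exploratory = 0.05,
                                fisher_tail = "greater") {
  cm <- tibble::as_tibble(as.data.frame(cluster_means))
  if (nrow(cm) != nrow(participants)) {
    stop("cluster means and participants must have the same rows")
  }
  tests <- list(
    list(var = "hit_rate", method = "spearman", groups = c("HC", "SZ")),
    list(var = "psychomotor_poverty", method = "spearman", groups = "SZ"),
    list(var = "disorganization", method = "spearman", groups = "SZ"),
    list(var = "reality_distortion", method = "spearman", groups = "SZ"),
    list(var = "sofas", method = "pearson", groups = "SZ"),
    list(var = "sspi_total", method = "pearson", groups = "SZ"),
    list(var = "dose_ddd", method = "spearman", groups = "SZ"),
    list(var = "lifetime_exposure", method = "spearman", groups = "SZ"))
  vars <- vapply(tests, `[[`, "", "var")
  missing <- setdiff(vars, names(participants))
  if (length(missing)) {
    stop("participants table missing score columns: ",
         paste(missing, collapse = ", "))
  }

  rows <- list()
  for (cl in names(cm)) {
    for (te in tests) {
      thr <- if (te$var %in% hypothesised) threshold_hypothesised else
        threshold_exploratory
      per_group <- list()
      for (g in te$groups) {
        sel <- participants$group == g & !is.na(participants[[te$var]]) &
          !is.na(cm[[cl]])
        if (sum(sel) < 4) next
        res <- correlate(cm[[cl]][sel], participants[[te$var]][sel], te$method)
        per_group[[g]] <- res
        rows[[length(rows) + 1]] <- tibble::tibble(
          cluster = cl, variable = te$var, group = g, method = te$method,
          estimate = res$r, n = res$n, df = res$df, p = res$p,
          threshold = thr, significant = res$p < thr)
      }
      if (te$var == "hit_rate" && all(c("HC", "SZ") %in% names(per_group))) {
        fz <- fisher_r_to_z_compare(per_group$HC$r, per_group$HC$n,
                                    per_group$SZ$r, per_group$SZ$n,
                                    tail = fisher_tail)
        rows[[length(rows) + 1]] <- tibble::tibble(
          cluster = cl, variable = te$var, group = "HC-vs-SZ",
          method = "fisher_rz", estimate = fz$z,
          n = per_group$HC$n + per_group$SZ$n, df = NA_integer_, p = fz$p,
          threshold = threshold_exploratory,
          significant = fz$p < threshold_exploratory)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("association_table", class(out))
  out
}
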