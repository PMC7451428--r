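#' Build an n-back block task design
#'
#' Lays out a block-design working-memory paradigm: each task block presents
#' the 0-back, 1-back and 2-back conditions (30 s each) in a randomised
#' order, separated by 10-s gaps whose first 2 s carry the on-screen
#' instruction, so each block spans 30 + 10 + 30 + 10 + 30 = 110 s. The
#' default layout is seven blocks per session over two sessions. Blocks are
#' contiguous within a session and onsets are session-relative.
#'
#' @param n_blocks_per_session Number of task blocks per session.
#' @param n_sessions Number of task sessions.
#' @param condition_s Duration of each n-back condition in seconds.
#' @param gap_s Gap between conditions in seconds (first `instruction_s`
#'   seconds of each gap are labelled `"instruction"`, the rest
#'   `"interval"`).
#' @param instruction_s Instruction-screen duration at the start of each gap.
#' @param rng_seed Optional integer seed controlling the condition order;
#'   identical seeds reproduce identical designs.
#'
#' @return A `task_design` object: a tibble with columns `label` (one of
#'   `"0-back"`, `"1-back"`, `"2-back"`, `"instruction"`, `"interval"`),
#'   `onset` (s, session-relative), `duration` (s), `session` and `block`,
#'   with attributes `n_sessions` and `session_duration` (s).
#'
#' @examples
#' d <- generate_task_design(rng_seed = 1)
#' subset(d, label == "2-back")
#' @export
generate_task_design <- function(n_blocks_per_session = 7,
                                 n_sessions = 2,
                                 condition_s = 30,
                                 gap_s = 10,
                                 instruction_s = 2,
                                 rng_seed = NULL) {
  if (!is_count(n_blocks_per_session)) stop("n_blocks_per_session must be a positive integer")
  if (!is_count(n_sessions)) stop("n_sessions must be a positive integer")
  stopifnot(condition_s > 0, gap_s >= 0, instruction_s >= 0, instruction_s <= gap_s)

  conditions <- c("0-back", "1-back", "2-back")
  block_span <- 3 * condition_s + 2 * gap_s

  rows <- with_seed(rng_seed, {
    out <- vector("list", n_sessions * n_blocks_per_session)
    k <- 0L
    for (s in seq_len(n_sessions)) {
      for (b in seq_len(n_blocks_per_session)) {
        ord <- sample(conditions)
        t0 <- (b - 1) * block_span
        lab <- character(0); on <- numeric(0); du <- numeric(0)
        for (i in 1:3) {
          lab <- c(lab, ord[i]); on <- c(on, t0); du <- c(du, condition_s)
          t0 <- t0 + condition_s
          if (i < 3) {
            if (instruction_s > 0) {
              lab <- c(lab, "instruction"); on <- c(on, t0); du <- c(du, instruction_s)
            }
            if (gap_s - instruction_s > 0) {
              lab <- c(lab, "interval"); on <- c(on, t0 + instruction_s)
              du <- c(du, gap_s - instruction_s)
            }
            t0 <- t0 + gap_s
          }
        }
        k <- k + 1L
        out[[k]] <- tibble::tibble(label = lab, onset = on, duration = du,
                                   session = s, block = b)
      }
    }
    dplyr::bind_rows(out)
  })

  new_task_design(rows, n_sessions = n_sessions,
                  session_duration = n_blocks_per_session * block_span)
}

new_task_design <- function(rows, n_sessions, session_duration) {
  d <- tibble::as_tibble(rows)
  required <- c("label", "onset", "duration", "session")
  missing <- setdiff(required, names(d))
  if (length(missing)) stop("task design missing columns: ", paste(missing, collapse = ", "))
  d <- dplyr::arrange(d, .data$session, .data$onset)
  # non-overlap within session
  by_sess <- split(d, d$session)
  for (s in by_sess) {
    ends <- s$onset + s$duration
    if (any(s$onset[-1] < ends[-nrow(s)] - 1e-9)) {
      stop("task design blocks overlap within a session")
    }
  }
  structure(d, class = c("task_design", class(d)),
            n_sessions = as.integer(n_sessions),
            session_duration = session_duration)
}

#' Condition windows of a task design
#'
#' @param design A `task_design`.
#' @param label Condition label to extract (default `"2-back"`).
#' @return Tibble with `session`, `onset`, `duration` for each window.
#' @export
condition_windows <- function(design, label = "2-back") {
  stopifnot(inherits(design, "task_design"))
  d <- design[design$label == label, c("session", "onset", "duration")]
  tibble::as_tibble(d)
}

# Indices (1-based, session-relative) of volumes whose acquisition midpoint
# falls inside [onset, onset + duration). Volume i spans [(i-1)*tr, i*tr).
volumes_in_window <- function(onset, duration, tr, n_vols) {
  mids <- (seq_len(n_vols) - 0.5) * tr
  which(mids >= onset & mids < onset + duration)
}

#' Number of volumes per session implied by a design
#' @param design A `task_design`.
#' @param tr Repetition time in seconds.
#' @return Integer volume count per session (ceiling of session duration / tr).
#' @export
session_n_vols <- function(design, tr) {
  stopifnot(inherits(design, "task_design"), tr > 0)
  as.integer(ceiling(attr(design, "session_duration") / tr))
}

#' Write / read a task design as TSV
#' @param design A `task_design`.
#' @param path File path.
#' @return `read_task_design` returns a `task_design`.
#' @export
write_task_design <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  df <- as.data.frame(design)
  df$n_sessions <- attr(design, "n_sessions")
  df$session_duration <- attr(design, "session_duration")
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_task_design
#' @export
read_task_design <- function(path) {
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE)
  ns <- df$n_sessions[1]
  sd_ <- df$session_duration[1]
  df$n_sessions <- NULL; df$session_duration <- NULL
  new_task_design(df, n_sessions = ns, session_duration = sd_)
}
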