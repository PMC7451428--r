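# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop("seed must be a single number or NULL")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a stage seed from a master seed, keeping the
# result a valid 32-bit integer.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 11L, motion = 23L, behaviour = 37L, embed = 41L,
               alphasim = 53L, design = 61L, noise = 71L, subject = 83L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    (sum(utf8ToInt(stage)) %% 1000L)
  (as.integer(seed) * 1000L + off) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# package-level memo cache for grid-dependent operators (smoothing matrices,
# voxel coordinate tables, task regressors); keyed by rlang::hash of inputs
.restshift_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  k <- rlang::hash(key)
  if (!is.null(.restshift_cache[[k]])) return(.restshift_cache[[k]])
  val <- force(expr)
  .restshift_cache[[k]] <- val
  val
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 1 && x == floor(x)
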