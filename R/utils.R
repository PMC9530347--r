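# Internal helpers: seeded substreams and small validators.

# Stable 32-bit hash of a stage name, combined with the user seed, so each
# pipeline stage gets its own reproducible RNG substream regardless of the
# order in which stages are called.
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  m <- 2147483563
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) %% m + h) %% m)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

assert_count_matrix <- function(counts, what = "counts") {
  if (!is.matrix(counts)) stop(what, " must be a matrix (cells x genes)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop(what, " must carry cell ids as rownames and gene ids as colnames")
  if (anyDuplicated(rownames(counts))) stop(what, ": duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stop(what, ": duplicate gene ids")
  if (any(counts < 0)) stop(what, ": negative entries")
  invisible(counts)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop("invalid ", name, ": must be a number in [", lo, ", ", hi, "]")
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop("invalid ", name, ": must be a positive number")
  invisible(x)
}

check_range <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || any(x <= 0) ||
      x[1] > x[2])
    stop("invalid ", name, ": must be (lo, hi) positive with lo <= hi")
  invisible(x)
}
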