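# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards. Keeps cohort generation reproducible without
# clobbering the session RNG.
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Run-length intervals of a logical vector: data.frame(start, end) of runs of
# TRUE, 1-based inclusive indices. Empty data.frame when no run.
runs_of <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("'%s' must be a single integer >= 1", name), call. = FALSE)
  invisible(TRUE)
}
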