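#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing errors go through stop() with
# call. = FALSE so messages name the offending argument, not the internals.

`%||%` <- function(a, b) if (is.null(a)) b else a

check_probability <- function(p, name) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(p)
}

check_count <- function(n, name, min = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < min ||
      n != round(n)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(n))
}

check_positive <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (x > 0 || (allow_zero && x == 0))
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number", name,
                 if (allow_zero) "non-negative" else "positive"),
         call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; a NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_count(seed, "seed", min = 0L)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
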