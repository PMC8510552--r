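#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL evaluates `expr` in the current
# stream (so callers can manage seeding themselves).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed, staying within 32-bit range.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# Lower-triangle unfold of a square matrix, the canonical pair vector used
# by all distance-matrix statistics in this package.
lower_vec <- function(m) m[lower.tri(m)]

check_square_aligned <- function(..., labels = NULL) {
  ms <- list(...)
  n <- nrow(ms[[1L]])
  for (m in ms) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop_invalid("distance matrices must be square")
    if (nrow(m) != n) stop_invalid("distance matrices must have matching size")
  }
  ids <- rownames(ms[[1L]])
  if (!is.null(ids)) {
    for (m in ms[-1L]) {
      if (!is.null(rownames(m)) && !identical(rownames(m), ids))
        stop_invalid("distance matrices must have matching id order")
    }
  }
  invisible(TRUE)
}
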