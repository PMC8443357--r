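# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed for a named random stream
#'
#' Every stage of the pipeline (sample splitting, synthetic data, CV fold
#' assignment, the GA) draws from its own stream derived from one root seed,
#' so stages are independently reproducible and reordering one stage does not
#' perturb another.
#'
#' @param seed Integer root seed.
#' @param stream One of `"split"`, `"synth"`, `"cv"`, `"ga"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, stream = c("split", "synth", "cv", "ga")) {
  stream <- match.arg(stream)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  off <- c(split = 101, synth = 211, cv = 307, ga = 401)[[stream]]
  as.integer((abs(as.numeric(seed)) %% 2147480000 * 31 + off) %% 2147483647)
}

# Run `code` under `seed` and restore the caller's RNG state afterwards, so
# seeded sub-operations (fold assignment, splits) never disturb an enclosing
# random stream such as the GA's.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  assert_scalar_number(x, name)
  if (x != floor(x) || x < min) {
    stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  }
  invisible(as.integer(x))
}
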