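#' @keywords internal
"_PACKAGE"

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards. All stochastic operations in the package route through this so
# that seeds are explicit arguments and no hidden global state leaks.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  invisible(x)
}
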