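# Scoped seeding. Functions that take a `seed` argument seed a local RNG
# stream and restore the caller's state on exit, so seeded calls are
# reproducible without disturbing surrounding simulations:
#   old <- .seed_begin(seed); on.exit(.seed_end(old), add = TRUE)
# A NULL seed leaves the RNG untouched.
.seed_begin <- function(seed) {
  if (is.null(seed)) return(list(noop = TRUE))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  list(noop = FALSE, old = old)
}

.seed_end <- function(state) {
  if (isTRUE(state$noop)) return(invisible(NULL))
  if (!is.null(state$old)) {
    assign(".Random.seed", state$old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  }
  invisible(NULL)
}
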