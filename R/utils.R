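# Run code under a fixed RNG seed without disturbing the caller's RNG state.
# All stochastic entry points in the package take an explicit seed and route
# through here, so nothing depends on (or mutates) the global stream.
with_seed <- function(seed, code) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("an explicit integer `seed` is required", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
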