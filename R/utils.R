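# small shared helpers

#' @useDynLib lesionseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Evaluate expr with a temporarily seeded RNG, restoring the caller's
# RNG state afterwards so library internals never disturb user code.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from one master seed, each below 2^31.
derive_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483629
}
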