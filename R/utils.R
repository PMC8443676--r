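# Seed the RNG for the calling function only, restoring the caller's
# RNG state when that function exits. A NULL seed leaves the RNG alone.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible())
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  restore <- if (has_old) {
    old <- get(".Random.seed", globalenv())
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible()
}
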