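# internal helpers shared across modules

#' @importFrom stats rpois runif sd t.test pt setNames
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# collapse runs of whitespace and trim; vectorised
squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_line <- function(msg, line) {
  stop(sprintf("%s (line %d)", msg, line), call. = FALSE)
}
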