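#' @importFrom stats rnorm runif sd setNames
#' @importFrom utils head modifyList
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Derive a child RNG seed from a base seed; stays inside 32-bit integer range.
derive_seed <- function(base, k) {
  as.integer(((as.double(base) + as.double(k) * 1000003) %% 2147483646) + 1)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

plog <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stop_stage <- function(stage, fmt, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(fmt, ...)), call. = FALSE)
}
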