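#' @useDynLib morphparsimony, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom ape read.tree write.tree
NULL

# Structured conditions: every domain error is a classed condition so callers
# (and tests) can distinguish e.g. a ragged matrix from an unknown symbol.
mp_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "morphparsimony_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

mp_warn <- function(class, msg, ...) {
  warning(structure(
    class = c(class, "morphparsimony_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Run code with a deterministic RNG stream without disturbing the caller's
# random-number state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}
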