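# Internal helpers: error conditions, seed derivation, misc.

omniprs_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "omniprs_error"),
                      call = call))
}

omniprs_warn <- function(msg, class = "omniprs_warning") {
  warning(warningCondition(msg, class = c(class, "omniprs_warning")))
}

#' Derive a stage seed from a root seed
#'
#' All randomness in the package flows from a single root seed. Each stage
#' (annotation, effects, each study, each random set, each permutation, ...)
#' receives its own seed derived deterministically from the root seed, a stage
#' tag and an index, so that stages can be re-run or reordered without
#' perturbing each other's random streams.
#'
#' The rule is a 31-bit multiplicative string hash: starting from the root
#' seed, fold in the UTF-8 code of each character of `tag`, then the index,
#' with multiplier 31 modulo `2^31 - 1`. Seeds are always in `[1, 2^31 - 2]`.
#'
#' @param seed integer root seed.
#' @param tag character stage tag, e.g. `"study"`.
#' @param index integer index within the stage (default 0).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, tag, index = 0L) {
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  s <- as.numeric(seed) %% m
  for (code in utf8ToInt(tag)) s <- (s * 31 + code) %% m
  s <- (s * 31 + as.numeric(index) %% m) %% m
  as.integer(s + 1)
}

# Evaluate `code` under a local RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
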