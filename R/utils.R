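#' @importFrom rlang .data
#' @importFrom generics tidy glance
NULL

# Set the RNG seed for the calling function without disturbing the caller's
# global RNG state; restoration happens when the calling frame exits.
local_rng <- function(seed, envir = parent.frame()) {
  if (!is.null(seed)) withr::local_seed(seed, .local_envir = envir)
  invisible(seed)
}

# Deterministic per-stage seed derived from a global seed. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
generics::tidy

#' @export
generics::glance
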