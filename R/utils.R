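#' Derive a reproducible child seed from a root seed
#'
#' Deterministic integer hashing used wherever one root seed must fan out
#' into independent per-replicate streams (power grids, pipeline stages).
#' Kept strictly below 2^31 so the result is a valid R integer seed.
#'
#' @param root integer root seed.
#' @param index non-negative integer stream index.
#' @return A positive integer seed.
#' @export
derive_seed <- function(root, index) {
  m <- 2147483647
  s <- (as.numeric(root) %% m) * 48271 %% m
  s <- (s + (as.numeric(index) %% m) * 69621) %% m
  as.integer(s %% (m - 1) + 1)
}

# internal: paste a site/station or site/year pair into a stable key
pair_key <- function(a, b) paste(a, b, sep = "\r")
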