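# Internal helpers shared across modules.

#' Derive a child seed from a master seed
#'
#' Fans one user-facing seed out to per-stage streams so that each pipeline
#' stage is reproducible in isolation. Kept below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param index Integer stream index (>= 1).
#' @return An integer seed.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 104729) %% 2147483647)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Linear-interpolation quartiles (type 7), fixed here for determinism.
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.75), names = FALSE, type = 7)
}
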