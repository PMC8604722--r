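#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; clinical report tables
#' conventionally round half up (e.g. 56.52\% prints as 57\%).
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a per-stream 32-bit seed from a master seed and a stream index.
# Substreams are fixed per patient index so enlarging a cohort never
# perturbs the records of existing patients.
derive_seed <- function(master_seed, stream, offset = 0L) {
  (as.numeric(master_seed) + 1000003 * stream + 7919 * offset) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid TrialConfig field '%s': %s", field, msg), call. = FALSE)
}
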