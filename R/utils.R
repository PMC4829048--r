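#' Round half away from zero
#'
#' Deterministic half-up rounding used wherever inferred-individual counts
#' are converted to integers. `base::round()` rounds half to even, which
#' gives e.g. `round(44.5) == 44`; demographic bookkeeping here always
#' rounds .5 upward in magnitude.
#'
#' @param x numeric vector
#' @return numeric vector of rounded values
#' @keywords internal
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(master, offset) {
  (as.integer(master) + 1000L * as.integer(offset)) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
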