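# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
}

# Sample SD with the n-1 denominator is used everywhere in the package;
# stats::sd already does this, the alias just makes the convention explicit.
sample_sd <- stats::sd

#' Derive a reproducible stage seed from a master seed
#'
#' Stages of the pipeline that use randomness (clustering restarts, gap
#' reference draws, bootstrap resampling) each get their own seed derived
#' from one master seed, so any stage can be re-run in isolation and still
#' reproduce the full-pipeline result. Kept below 2^31 - 1 so the value is a
#' valid R integer.
#'
#' @param seed master integer seed.
#' @param stage integer stage offset (>= 0).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, stage) {
  abort_if(!is.numeric(seed) || length(seed) != 1L, "`seed` must be a single integer")
  as.integer((abs(as.numeric(seed)) * 1009 + 97 * as.numeric(stage)) %% 2147483629)
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)
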