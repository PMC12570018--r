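`%||%` <- function(x, y) if (is.null(x)) y else x

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

#' Derive a reproducible substream seed
#'
#' Independent per-purpose random substreams are derived from one master seed
#' so that changing the parameters of one simulation stage does not perturb
#' the draws of another.
#'
#' @param seed master integer seed
#' @param stream small integer index of the substream
#' @return an integer seed below 2^31
#' @keywords internal
.substream_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * stream) %% 2147483647L)
}

.is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
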