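#' Round half-up to the nearest integer
#'
#' The rounding rule used to integerize mean copy numbers into parsimony
#' states: 2.5 rounds to 3 (base R's `round` would give 2).
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @export
round_half_up <- function(x) as.integer(floor(x + 0.5))
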