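#' @importFrom stats rnorm runif rgamma rchisq sd var qt qnorm pnorm plogis
#'   qlogis uniroot optimize optimHess quantile lm.fit setNames rbinom
#'   complete.cases aggregate
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

is_probability <- function(p) is.numeric(p) && length(p) == 1 && !is.na(p) && p >= 0 && p <= 1

#' Derive a stream-specific seed from a master seed
#'
#' Keeps derived seeds in the 32-bit integer range so the same master seed
#' can drive several independent generation steps deterministically.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629) + 1L
}
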