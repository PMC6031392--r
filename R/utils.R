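#' @keywords internal
"_PACKAGE"

#' @importFrom stats runif setNames sd as.dist
#' @importFrom utils modifyList head tail combn read.delim
NULL

# Derive a reproducible child seed (< 2^31) from a global seed and a stage
# name, so pipeline stages can be rerun independently yet reproducibly.
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) %% 1000003) * 2017 + h) %% 2147483587L
}

# Round half away from zero (the convention of the printed tables; base R
# round() is banker's rounding).
round_half_away <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
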