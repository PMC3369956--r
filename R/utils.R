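#' @keywords internal
"_PACKAGE"

#' @importFrom stats median mad pnorm qnorm p.adjust phyper rnorm rmultinom
#'   density rbinom sd t.test runif setNames
#' @importFrom utils head tail read.delim write.table read.csv write.csv
NULL

# Uniform invalid-parameter error helper: all user-facing validation errors go
# through here so messages carry the function context.
stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_fraction <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Derive a stage-specific seed from a single top-level seed so all stages of a
# pipeline are reproducible from one integer. Kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is_count(seed)) stop_invalid("seed must be a single non-negative integer")
    set.seed(as.integer(seed))
  }
  expr
}
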