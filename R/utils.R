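#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr %>%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n row_number across all_of desc
#' @importFrom tibble tibble as_tibble
#' @import ggplot2
NULL

# Round half away from zero, as spreadsheet-style table formatting does.
# base round() rounds half to even, which disagrees at e.g. 0.625 -> 0.62.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible 31-bit sub-seed from a master seed and a label, so
# that e.g. each simulated sample gets its own independent RNG substream.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(paste0("s", label))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer((seed * 2654435 + h) %% 2147483647)
}

# Intersect two sets of disjoint 0-based half-open intervals (matrices /
# data frames with start0, end0). Returns a tibble sorted by start0.
intersect_intervals <- function(a, b) {
  ra <- IRanges::IRanges(start = a$start0 + 1L, end = a$end0)
  rb <- IRanges::IRanges(start = b$start0 + 1L, end = b$end0)
  ri <- IRanges::reduce(IRanges::intersect(ra, rb))
  tibble(start0 = BiocGenerics::start(ri) - 1L, end0 = BiocGenerics::end(ri))
}

# Total bp covered by the union of 0-based half-open intervals.
union_width <- function(start0, end0) {
  if (length(start0) == 0) return(0L)
  r <- IRanges::reduce(IRanges::IRanges(start = start0 + 1L, end = end0))
  sum(BiocGenerics::width(r))
}

`%not_in%` <- function(x, table) !(x %in% table)

stop_if_not <- function(cond, msg) {
  if (!cond) abort(msg)
}
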