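#' Percentage of a count within a total
#'
#' Bookkeeping helper used throughout the per-sample and per-CpG summaries:
#' `count / total * 100`, optionally rounded to the precision at which cohort
#' tables are usually reported.
#'
#' @param count Numeric count (or vector of counts).
#' @param total Positive total the counts are taken from.
#' @param digits Number of decimal digits to round to, or `NULL` for no
#'   rounding (default).
#' @return Numeric percentage(s) in `[0, 100]`.
#' @examples
#' percentage(143101, 670233, digits = 2)
#' @export
percentage <- function(count, total, digits = NULL) {
  stopifnot(is.numeric(count), is.numeric(total), length(total) == 1L,
            total > 0, all(count >= 0))
  p <- count / total * 100
  if (!is.null(digits)) p <- round(p, digits)
  p
}

#' Class percentages from class counts
#'
#' Converts a vector of methylation-class counts (hypo/semi/hyper) into
#' percentages of their sum. Percentages sum to 100 exactly (before rounding).
#'
#' @param counts Named non-negative numeric vector with a positive sum.
#' @inheritParams percentage
#' @return Named numeric vector of percentages.
#' @examples
#' class_percentages(c(hypo = 143101, semi = 384689, hyper = 142443), digits = 2)
#' @export
class_percentages <- function(counts, digits = NULL) {
  stopifnot(is.numeric(counts), all(counts >= 0), sum(counts) > 0)
  percentage(counts, sum(counts), digits = digits)
}

# Trapezoid-rule integral on an ordered grid. Written out because the
# 1023-subinterval trapezoid integration is part of the published MVS
# definition, not incidental numerics.
trapezoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L, !is.unsorted(x))
  n <- length(x)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All generators go through this so that a config
# seed fully determines the output without disturbing the session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive independent substream seeds from one master seed, so the three
# generators can share a single user-facing seed without coupling.
substream_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
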