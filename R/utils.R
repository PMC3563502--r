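#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for all percentage cells in the
#' pipeline's tables. `base::round()` rounds half to even, which would turn
#' e.g. 12.5 into 12; table formatting here requires 12.5 -> 13.
#'
#' @param x numeric vector (non-negative in all pipeline uses).
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon guards against values like 78.4 stored as 78.3999...
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a total, rounded half-up
#'
#' @param num count (numerator).
#' @param den total (denominator).
#' @param digits decimal places (2 matches the published table style).
#' @return numeric percentage; `NA` where `den` is 0.
#' @export
percent_of <- function(num, den, digits = 2) {
  n <- max(length(num), length(den))
  num <- rep_len(num, n)
  den <- rep_len(den, n)
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, digits))
}

#' Format a "count (percent%)" table cell
#'
#' @param num count.
#' @param den total.
#' @param digits decimal places for the percentage.
#' @return character vector like `"19 (52.78%)"`; `"N/A"` where `num` is `NA`.
#' @export
fmt_count_pct <- function(num, den, digits = 2) {
  pct <- percent_of(num, den, digits)
  out <- ifelse(
    is.na(num), "N/A",
    sprintf(paste0("%d (%.", digits, "f%%)"), num, ifelse(is.na(pct), 0, pct))
  )
  out
}

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# Every generator in the package routes its randomness through this, so no
# global random state leaks between calls and equal seeds give equal output.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with a stage prefix so pipeline aborts name the failing stage
stage_stop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
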