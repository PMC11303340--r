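#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run an expression under a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Percentage of a count against a denominator, rendered to two decimals.
#'
#' The convention used throughout descriptive outputs: `100 * count / denom`
#' rounded half-up-ish via [round()] to 2 decimals. `denom = 0` yields `NA`.
#'
#' @param count,denom numeric vectors (recycled).
#' @return numeric vector of percentages.
#' @export
#' @examples
#' pct2(21320, 35923)
pct2 <- function(count, denom) {
  out <- 100 * count / denom
  out[denom == 0] <- NA_real_
  round(out, 2)
}

#' @noRd
log_msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}
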