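# Shared numeric and formatting conventions.

#' Round half away from zero
#'
#' Deterministic "half-up" rounding used for every rendered percentage and
#' mean in this package, so that e.g. `1.425` renders as `1.43`. Base R's
#' `round()` rounds half to even, which disagrees with how comparison tables
#' in the phasing literature are typically printed.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(1.425, 2.5, -2.5), c(2, 0, 0))
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a percentage to two decimals, half-up
#'
#' @param x Percentage values (already on the 0--100 scale).
#' @param digits Decimal places (default 2).
#' @return Character vector like `"38.07"`.
#' @export
format_pct <- function(x, digits = 2) {
  out <- sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
  out[is.na(x)] <- NA_character_
  out
}

#' Format counts and percentages the way comparison tables print them
#'
#' `format_count()` adds thousands separators for human-readable rendering
#' (never used in machine-readable TSV). `format_count_pct()` renders a
#' disagreement cell as `"459/32,150 (1.43%)"`; with `denominator = NULL`
#' it renders an overlap cell as `"43,868 (38.07%)"`.
#'
#' @param n,count,denominator Non-negative integer counts.
#' @param big_mark Thousands separator; use `""` for machine output.
#' @return Character vector.
#' @export
format_count <- function(n, big_mark = ",") {
  out <- formatC(n, format = "d", big.mark = big_mark)
  out[is.na(n)] <- NA_character_
  out
}

#' @rdname format_count
#' @export
format_count_pct <- function(count, denominator = NULL, big_mark = ",") {
  if (is.null(denominator)) {
    stop("format_count_pct() needs an explicit denominator or a rate")
  }
  pct <- format_pct(100 * count / denominator)
  paste0(
    format_count(count, big_mark), "/", format_count(denominator, big_mark),
    " (", pct, "%)"
  )
}

#' @rdname format_count
#' @param pct Pre-computed percentage for the `"count (pct%)"` layout.
#' @export
format_overlap_cell <- function(count, pct, big_mark = ",") {
  paste0(format_count(count, big_mark), " (", format_pct(pct), "%)")
}

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
# Keeps all simulation functions pure in (config, seed) with no global
# random-state leakage.
with_rng_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Consistent error helper: all package errors carry a subclass so callers
# (and the CLI) can distinguish usage errors from data errors.
hc_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("hapcompare_", class), "hapcompare_error"), ...)
}

stopifnot_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    hc_abort(paste0("`", what, "` must be a single string"), "usage_error")
  }
  invisible(x)
}
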