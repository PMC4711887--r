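# Shared small helpers.

#' Round a percentage half-up to one decimal
#'
#' Percentages throughout the summary tables are stored at one decimal with
#' half-up rounding (so 0.96745 of a total prints as 96.7, and 26,995 of
#' 27,113 prints as 99.6). Base `round()` rounds half to even, which is the
#' wrong convention for reproducing printed tables.
#'
#' @param count numerator count.
#' @param total denominator count; `pct1(0, 0)` is defined as 0.
#' @return numeric percentage rounded half-up to one decimal.
#' @export
#' @examples
#' pct1(967, 1000)  # 96.7
pct1 <- function(count, total) {
  n <- max(length(count), length(total))
  count <- rep_len(count, n)
  total <- rep_len(total, n)
  out <- floor(count / total * 1000 + 0.5) / 10
  out[total == 0] <- 0
  out
}

# Half-up rounding to integer (base round() is half-to-even).
round_half_up <- function(x) floor(x + 0.5)

# Collapse runs of whitespace to single spaces and trim ends.
squish <- function(x) stringr::str_squish(x)

# TRUE where x has non-whitespace content.
is_filled <- function(x) !is.na(x) & nzchar(trimws(x))

# Replace NA with "" (verbatim fields are empty strings, never NA).
blank_na <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Abort with a classed condition so callers can test error categories.
tv_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "taxonvet_error"), ...)
}
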