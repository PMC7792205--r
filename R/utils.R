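#' Parse a fraction written as a decimal or a percent string
#'
#' Scenario files may express fractions either as decimals (`0.26`) or as
#' percent strings (`"26%"`); both parse to the same value. Percent strings
#' are divided by 100, so `"0.008%"` parses to `0.00008`.
#'
#' @param x A numeric, or a character vector of decimals / `"x%"` tokens.
#' @return A numeric vector of fractions.
#' @export
#' @examples
#' parse_fraction(c("26%", "0.26", "0.008%"))
parse_fraction <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  raw <- sub("%$", "", x)
  val <- suppressWarnings(as.numeric(raw))
  bad <- is.na(val) & !is.na(x)
  if (any(bad)) {
    rlang::abort(
      sprintf("cannot parse fraction from token '%s'", x[bad][1]),
      class = "sroikit_parse_error"
    )
  }
  ifelse(pct, val / 100, val)
}

fmt_money <- function(x, digits = 0) {
  formatC(round(x, digits),
          format = "f", digits = digits, big.mark = ",")
}

# full-precision decimal representation that survives a parse round trip
fmt_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (is.integer(v) || (is.finite(v) && v == round(v) && abs(v) < 2^53)) {
      return(format(v, scientific = FALSE))
    }
    format(v, digits = 17, scientific = FALSE)
  }, character(1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

effective_bf_rate <- function(s) {
  if (isTRUE(s$apply_breastfeeding_rate) && !is.na(s$breastfeeding_rate)) {
    s$breastfeeding_rate
  } else {
    1
  }
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

log_warn <- function(...) log_msg("WARN", ...)
log_info <- function(...) log_msg("INFO", ...)
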