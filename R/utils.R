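#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# round half away from zero (tables are formatted this way; base round() is
# round-half-even)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Round-half-away-from-zero percentage formatting
#'
#' Percentages in the summary tables are displayed at one decimal with ties
#' rounded away from zero (so 31.35 prints as 31.4). Internal columns keep
#' full precision; call this only at the reporting edge.
#'
#' @param x Numeric vector of percentages.
#' @param digits Number of decimals (default 1).
#' @return Numeric vector rounded half-away-from-zero.
#' @export
#' @examples
#' format_pct(c(31.35, 29.787))
format_pct <- function(x, digits = 1) round_half_up(x, digits)

# stop with a class so tests can assert on error families
stop_offlabelr <- function(msg, class = "offlabelr_error") {
  abort(msg, class = c(class, "offlabelr_error"))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_offlabelr(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      class = "offlabelr_validation_error"
    )
  }
}
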