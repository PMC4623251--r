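#' Round half away from zero
#'
#' Presentation rounding used throughout the reports: halves round away from
#' zero (so 790.5 -> 791), unlike [base::round()]'s round-half-even. All model
#' arithmetic is carried at full precision; this is applied only when a table
#' or summary is rendered.
#'
#' @param x numeric vector.
#' @param digits integer; decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(790.5)  # 791, where round() gives 790
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# num %||% default for optional config fields
`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  }
  invisible(x)
}
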