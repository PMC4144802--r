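#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used for all printed statistics in this package), unlike [base::round()]
#' which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_up(0.125, 2)  # 0.13
#' round(0.125, 2)          # 0.12 (banker's rounding)
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Transition/transversion ratio
#'
#' @param ts,tv non-negative counts of transitions and transversions.
#' @param digits decimals for reporting (half-away-from-zero); `NULL` for
#'   the unrounded ratio.
#' @return `ts/tv`, or `NA_real_` when `tv` is zero (undefined).
#' @export
ts_tv_ratio <- function(ts, tv, digits = 2) {
  if (tv == 0) return(NA_real_)
  r <- ts / tv
  if (is.null(digits)) r else round_half_up(r, digits)
}

#' Percentage share of a total
#'
#' Convenience for headline statistics of the form "x accounts for p% of y",
#' e.g. the share of a genome-wide length difference attributable to one
#' intergenic spacer.
#'
#' @param part,total numeric; `total` must be non-zero.
#' @param digits decimals for reporting (default whole percent).
#' @return percentage on the 0-100 scale.
#' @export
percent_share <- function(part, total, digits = 0) {
  stopifnot(total != 0)
  round_half_up(100 * part / total, digits)
}

## reverse complement on plain character strings (internal; Biostrings-backed)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## split a string into a character vector of single bases
str2chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

chars2str <- function(x) paste(x, collapse = "")

## is {a,b} a transition pair?
is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

## run-length intervals of TRUE values: matrix with columns start, end (1-based
## inclusive); zero-row matrix when none
true_runs <- function(flags) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
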