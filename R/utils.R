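#' @keywords internal
"_PACKAGE"

# Shared input checks -------------------------------------------------------

stop_ds <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_ds("'%s' must be a single non-missing number", name)
  if (finite && !is.finite(x)) stop_ds("'%s' must be finite", name)
  if (positive && x <= 0) stop_ds("'%s' must be > 0 (got %g)", name, x)
  invisible(x)
}

check_probability_vector <- function(x, name) {
  if (length(x) == 0L) stop_ds("'%s' is empty", name)
  if (anyNA(x) || any(x < 0 | x > 1))
    stop_ds("'%s' has values outside [0, 1]", name)
  invisible(x)
}

#' Express a count ratio as a percentage
#'
#' Utility used throughout the cohort reports: `count_percent(68, 181)` is
#' the percentage of a subgroup within a cohort, rounded to a fixed number
#' of decimal places for tabulation.
#'
#' @param numerator,denominator Non-negative counts, `numerator <= denominator`.
#' @param digits Decimal places to round to (default 2).
#' @return A single number, `100 * numerator / denominator`, rounded.
#' @examples
#' count_percent(68, 181)  # 37.57
#' @export
count_percent <- function(numerator, denominator, digits = 2) {
  check_scalar_number(numerator, "numerator")
  check_scalar_number(denominator, "denominator", positive = TRUE)
  if (numerator < 0 || numerator > denominator)
    stop_ds("numerator must lie in [0, denominator]")
  round(100 * numerator / denominator, digits)
}

# The 20 standard amino acids, alphabetical by one-letter code.
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_sequence <- function(sequence, name = "sequence", allow_x = TRUE) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop_ds("'%s' must be a single string", name)
  if (nchar(sequence) == 0L) stop_ds("'%s' is empty", name)
  letters_ok <- c(AA_LETTERS, if (allow_x) "X")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), letters_ok)
  if (length(bad))
    stop_ds("'%s' contains invalid residue(s): %s", name,
            paste(sQuote(bad), collapse = ", "))
  invisible(chars)
}
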