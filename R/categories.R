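# Ordered categorical scales shared by the whole pipeline. All rule logic
# works on these factors; free-text tokens are validated at the boundary.

RADS_LEVELS <- c("2", "3", "4A", "4B", "4X")
GVR_LEVELS <- c("I", "II", "III", "IV")
BIN_LEVELS <- c("low", "medium", "high")
TRUTH_LEVELS <- c("non-neoplastic", "neoplastic")
SPLIT_LEVELS <- c("training", "validation")

#' Category scales used by the stratification rules
#'
#' `rads_categories()` returns the ordered risk-category labels
#' (2 < 3 < 4A < 4B < 4X), `gvr_types()` the four GGN-vessel-relationship
#' types (I pass-by, II pass-through, III distorted/dilated, IV
#' complicated), and `dl_risk_bins()` the ordered malignancy-score bins
#' (low < medium < high).
#'
#' @return A character vector of admissible labels, in order.
#' @export
rads_categories <- function() RADS_LEVELS

#' @rdname rads_categories
#' @export
gvr_types <- function() GVR_LEVELS

#' @rdname rads_categories
#' @export
dl_risk_bins <- function() BIN_LEVELS

#' Coerce labels to validated ordered factors
#'
#' `rads_factor()`, `gvr_factor()` and `bin_factor()` coerce character or
#' factor input to the package's ordered scales, failing loudly on any
#' token outside the admissible set ("4a" and "iv" style lower case is
#' accepted and normalised).
#'
#' @param x character or factor vector of labels.
#' @return An ordered factor on the corresponding scale.
#' @export
rads_factor <- function(x) {
  ord_factor(toupper(as.character(x)), RADS_LEVELS, "Lung-RADS category")
}

#' @rdname rads_factor
#' @export
gvr_factor <- function(x) {
  ord_factor(toupper(as.character(x)), GVR_LEVELS, "GVR type")
}

#' @rdname rads_factor
#' @export
bin_factor <- function(x) {
  ord_factor(tolower(as.character(x)), BIN_LEVELS, "risk bin")
}

ord_factor <- function(x, levels, what) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s token(s): %s (admissible: %s)", what,
      paste(unique(x[bad]), collapse = ", "),
      paste(levels, collapse = ", ")
    ), call. = FALSE)
  }
  factor(x, levels = levels, ordered = TRUE)
}

# rank on the risk-category scale; vectorised, NA-safe
rads_rank <- function(x) match(as.character(x), RADS_LEVELS)

#' Round half up
#'
#' Deterministic commercial rounding (0.5 always rounds away from zero),
#' used by the report layer so that printed percentages match the usual
#' clinical-table convention rather than banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small fuzz absorbs binary representation error just below .5 boundaries
  sign(x) * floor(abs(x) * p + 0.5 + 1e-7) / p
}

#' Format a fraction as a percentage
#'
#' Report-layer conversion of a proportion in `[0, 1]` (or a correlation in
#' `[-1, 1]`) to the percent scale, rounded half-up.
#'
#' @param x numeric vector of fractions.
#' @param digits decimal places on the percent scale (default 2).
#' @return Numeric vector on the percent scale.
#' @examples
#' percent(537 / 561) # 95.72
#' @export
percent <- function(x, digits = 2) round_half_up(100 * x, digits)
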