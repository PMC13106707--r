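#' BMI category levels
#'
#' Ordered WHO weight-status categories used throughout the package:
#' underweight (< 18.5 kg/m^2), normal (18.5-25), overweight (25-30),
#' obese (>= 30). Ordinal codes 0-3 follow BMI order.
#'
#' @export
bmi_levels <- function() c("underweight", "normal", "overweight", "obese")

#' Assign a WHO BMI category
#'
#' Classifies body-mass index into the four WHO weight-status categories using
#' half-open intervals with an inclusive lower bound: underweight `[0, 18.5)`,
#' normal `[18.5, 25)`, overweight `[25, 30)`, obese `[30, Inf)`. The half-open
#' convention covers the whole positive line (a printed "18.5-24.9" band would
#' leave e.g. 24.95 unassigned).
#'
#' @param bmi numeric vector of BMI values in kg/m^2; must be finite and > 0.
#' @return an ordered factor with levels [bmi_levels()].
#' @examples
#' assign_bmi_category(c(18.4, 18.5, 25, 30))
#' @export
assign_bmi_category <- function(bmi) {
  if (!is.numeric(bmi)) stop("`bmi` must be numeric", call. = FALSE)
  if (length(bmi) == 0L) {
    return(factor(character(), levels = bmi_levels(), ordered = TRUE))
  }
  if (any(!is.finite(bmi)) || any(bmi <= 0)) {
    stop("`bmi` must be finite and positive", call. = FALSE)
  }
  cut(bmi,
    breaks = c(0, 18.5, 25, 30, Inf),
    labels = bmi_levels(),
    right = FALSE, ordered_result = TRUE
  )
}

#' Ordinal code of a BMI category
#'
#' @param category factor or character vector of categories.
#' @return integer codes 0 (underweight) through 3 (obese).
#' @export
bmi_category_code <- function(category) {
  if (!is.factor(category)) {
    category <- factor(category, levels = bmi_levels(), ordered = TRUE)
  }
  if (anyNA(category)) stop("unknown BMI category", call. = FALSE)
  as.integer(category) - 1L
}
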