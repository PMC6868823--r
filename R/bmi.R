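#' BMI class labels, in increasing order
#'
#' @return Character vector `c("underweight", "normal", "overweight", "obese")`.
#' @export
bmi_classes <- function() {
  c("underweight", "normal", "overweight", "obese")
}

#' Classify a BMI value into the four WHO classes
#'
#' Cutoffs follow WHO convention with half-open intervals:
#' underweight `[0, 18.5)`, normal `[18.5, 25)`, overweight `[25, 30)`,
#' obese `[30, Inf)`. The published cutpoints leave the gaps (24.9, 25.0)
#' and (29.9, 30.0] unstated; the half-open convention keeps the classes
#' contiguous and puts BMI exactly 30 in the obese class.
#'
#' @param bmi Numeric vector of BMI values in kg/m^2. Must be finite,
#'   positive, and at most 100 (a guard against weight-for-BMI unit errors).
#' @return Factor with levels [bmi_classes()], ordered.
#' @export
#' @examples
#' classify_bmi(c(16.5, 21, 27, 34))
classify_bmi <- function(bmi) {
  if (!is.numeric(bmi) || length(bmi) == 0) {
    stop("bmi must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- !is.finite(bmi) | bmi <= 0 | bmi > 100
  if (any(bad)) {
    stop(sprintf("invalid BMI value(s): %s (must be finite, > 0 and <= 100 kg/m^2)",
                 paste(utils::head(bmi[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  cut(bmi, breaks = c(0, 18.5, 25, 30, Inf), right = FALSE,
      labels = bmi_classes(), ordered_result = TRUE)
}
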