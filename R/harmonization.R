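#' Left ventricular ejection fraction by the Teichholz formula
#'
#' Converts M-mode linear dimensions to volumes by the Teichholz cube
#' correction, `V = 7.0 / (2.4 + D) * D^3` (D in cm, V in ml), and returns
#' the ejection fraction `100 * (EDV - ESV) / EDV` in percent.
#'
#' @param lvedd LV end-diastolic dimension, cm. Vectorised.
#' @param lvesd LV end-systolic dimension, cm. Vectorised.
#' @return LVEF in percent.
#' @export
teichholz_lvef <- function(lvedd, lvesd) {
  if (any(!is.finite(lvedd)) || any(!is.finite(lvesd))) {
    stop_data("non-finite LV dimensions")
  }
  if (any(lvesd <= 0) || any(lvedd >= 10)) {
    stop_data("LV dimensions must satisfy 0 < lvesd < lvedd < 10 cm")
  }
  if (any(lvesd >= lvedd)) {
    stop_data("lvesd must be strictly smaller than lvedd (negative EF not emitted)")
  }
  vol <- function(d) 7.0 / (2.4 + d) * d^3
  edv <- vol(lvedd)
  esv <- vol(lvesd)
  100 * (edv - esv) / edv
}

#' Fit a linear recalibration map by moment alignment
#'
#' Returns the affine map that takes the baseline distribution's mean and
#' SD onto supplied reference moments: `slope = ref_sd / base_sd`,
#' `intercept = ref_mean - slope * base_mean`. Used to put baseline-visit
#' echo measures on the later-visit measurement scale when only
#' distributional moments of the reference are available.
#'
#' @param baseline_values Numeric vector of baseline measures (NAs dropped).
#' @param reference_mean,reference_sd Target moments in measure units.
#' @param measure Label carried on the map (`"lvef"` or `"ea"`).
#' @return An object of class `linear_map` with fields `slope`,
#'   `intercept`, `measure`.
#' @export
fit_recalibration <- function(baseline_values, reference_mean, reference_sd,
                              measure = c("lvef", "ea")) {
  measure <- match.arg(measure)
  v <- baseline_values[is.finite(baseline_values)]
  if (length(v) < 10) stop_data("need >= 10 finite baseline values")
  base_sd <- stats::sd(v)
  if (base_sd <= 0) stop_data("baseline values have zero spread")
  if (!is.finite(reference_sd) || reference_sd <= 0) {
    stop_config("reference_sd", "must be a positive number")
  }
  slope <- reference_sd / base_sd
  structure(list(slope = slope,
                 intercept = reference_mean - slope * mean(v),
                 measure = measure),
            class = "linear_map")
}

#' Apply a linear recalibration map
#'
#' @param map A [fit_recalibration()] result.
#' @param values Numeric vector; missing values pass through as missing.
#' @return Recalibrated vector `slope * values + intercept`.
#' @export
apply_recalibration <- function(map, values) {
  stopifnot(inherits(map, "linear_map"))
  map$slope * values + map$intercept
}
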