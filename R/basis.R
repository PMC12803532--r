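#' Standardised-age polynomial basis
#'
#' The trajectory mixture regresses each echocardiographic target on a
#' low-degree polynomial in standardised age \eqn{z = (age - reference) /
#' scale}. Centring near the cohort's mid follow-up age and scaling by a
#' decade keeps the design well conditioned and makes coefficients
#' readable: the intercept is the target value at the reference age and
#' the linear coefficient is the change per `scale` years.
#'
#' @param reference_age Centre of the basis in years (default 70).
#' @param scale Age scale in years (default 10, i.e. one decade).
#' @param degree Polynomial degree, one of 0, 1, 2 (default 2).
#' @return An object of class `age_basis`.
#' @export
age_basis <- function(reference_age = 70, scale = 10, degree = 2) {
  if (!is.finite(scale) || scale <= 0) stop_config("scale", "must be > 0")
  if (!degree %in% 0:2) stop_config("degree", "must be 0, 1 or 2")
  structure(list(reference_age = reference_age, scale = scale,
                 degree = as.integer(degree)),
            class = "age_basis")
}

#' Evaluate the age basis at one or more ages
#'
#' @param age Numeric vector of ages in years.
#' @param basis An [age_basis()].
#' @return A matrix with `length(age)` rows and `degree + 1` columns
#'   `(1, z, z^2, ...)`.
#' @export
build_design <- function(age, basis) {
  stopifnot(inherits(basis, "age_basis"))
  if (any(!is.finite(age))) stop_data("non-finite age in design construction")
  z <- (age - basis$reference_age) / basis$scale
  X <- outer(z, 0:basis$degree, `^`)
  colnames(X) <- paste0("z", 0:basis$degree)
  X
}
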