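#' Piecewise log/linear age transformation
#'
#' Maps chronological age onto the epigenetic scale used as the regression
#' response. Methylation changes rapidly through childhood and adolescence and
#' roughly linearly in adults, so ages at or below the adult cut-off
#' \eqn{y_{c,adult}} are log-transformed and ages above it are scaled
#' linearly:
#' \deqn{f(y_c) = \log(y_c + 1) - \log(y_{c,adult} + 1) \quad (y_c \le y_{c,adult})}
#' \deqn{f(y_c) = (y_c - y_{c,adult}) / (y_{c,adult} + 1) \quad (y_c > y_{c,adult})}
#' The two branches meet at the cut-off with matching value (0) and slope
#' (\eqn{1/(y_{c,adult}+1)}), so the transform is continuous and once
#' differentiable there. A cut-off of 0 reduces to the identity on
#' non-negative ages, i.e. the standard linear model.
#'
#' @param age Numeric vector of chronological ages in years, all \eqn{\ge 0}.
#' @param cutoff Adult cut-off \eqn{y_{c,adult}} in years, a single value
#'   \eqn{\ge 0}. Default 20, the conventional choice.
#' @return Numeric vector of epigenetic-scale values (dimensionless).
#' @seealso [horvath_inverse()] for the exact inverse.
#' @examples
#' horvath_transform(c(0, 20, 41), cutoff = 20)
#' horvath_transform(33, cutoff = 0)  # identity
#' @export
horvath_transform <- function(age, cutoff = 20) {
  stopifnot(is.numeric(age), is.numeric(cutoff), length(cutoff) == 1L)
  if (is.na(cutoff) || cutoff < 0) {
    stop("`cutoff` must be a non-negative number of years.", call. = FALSE)
  }
  bad <- !is.na(age) & age < 0
  if (any(bad)) {
    stop("Chronological ages must be non-negative; got ",
         paste(utils::head(age[bad], 3L), collapse = ", "), call. = FALSE)
  }
  # boundary age == cutoff goes to the log branch; both branches agree there
  ifelse(age <= cutoff,
         log(age + 1) - log(cutoff + 1),
         (age - cutoff) / (cutoff + 1))
}

#' Inverse of the log/linear age transformation
#'
#' Maps an epigenetic-scale value back to chronological age in years:
#' non-negative values are on the linear branch
#' (\eqn{y_c = y_e (y_{c,adult}+1) + y_{c,adult}}), negative values on the
#' logarithmic branch (\eqn{y_c = \exp(y_e + \log(y_{c,adult}+1)) - 1}).
#' Exact inverse of [horvath_transform()] for ages \eqn{\ge 0}; defined for
#' every real input, with output always strictly greater than \eqn{-1}.
#' Strongly negative epigenetic values therefore map to (biologically
#' impossible) negative ages, which are returned as-is rather than clamped so
#' that callers can flag them.
#'
#' @param value Numeric vector of epigenetic-scale values.
#' @inheritParams horvath_transform
#' @return Numeric vector of chronological ages in years.
#' @examples
#' horvath_inverse(c(-1.588, 0, 1), cutoff = 20)
#' @export
horvath_inverse <- function(value, cutoff = 20) {
  stopifnot(is.numeric(value), is.numeric(cutoff), length(cutoff) == 1L)
  if (is.na(cutoff) || cutoff < 0) {
    stop("`cutoff` must be a non-negative number of years.", call. = FALSE)
  }
  ifelse(value >= 0,
         value * (cutoff + 1) + cutoff,
         exp(value + log(cutoff + 1)) - 1)
}
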