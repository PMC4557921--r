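# Logit-scale transforms with delta-method variances. All state-year survey
# estimates are modelled on the logit scale so that back-transformed trends
# stay inside (0, 1); variances travel through the transform by the delta
# method: var(logit p) = var(p) / (p(1-p))^2.

#' Clamp proportions into the modelling band
#'
#' Survey tabulations from small state samples can produce cells with p = 0 or
#' p = 1, whose logit is infinite. Estimates are clamped into
#' `[lower, upper]` before transformation; the default band is
#' \[0.001, 0.999\]. Pre-policy pseudo-observations (p = 1e-4) are created
#' below the floor deliberately and are exempt from this clamp.
#'
#' @param p numeric vector of proportions.
#' @param lower,upper clamp bounds.
#' @return clamped numeric vector.
#' @export
clamp_proportion <- function(p, lower = 0.001, upper = 0.999) {
  pmin(pmax(p, lower), upper)
}

#' Logit transform of a proportion estimate with its sampling variance
#'
#' @param p proportion(s) strictly inside (0, 1).
#' @param var_p positive sampling variance(s) of `p`.
#' @return a tibble with columns `y` (logit of p) and `var_y` (delta-method
#'   variance).
#' @export
to_logit <- function(p, var_p) {
  if (any(p <= 0 | p >= 1)) {
    stop("`p` must lie strictly inside (0, 1); clamp upstream first.")
  }
  if (any(var_p <= 0)) {
    stop("`var_p` must be positive.")
  }
  tibble::tibble(y = qlogis(p), var_y = var_p / (p * (1 - p))^2)
}

#' Inverse-logit transform with the reverse delta-method variance
#'
#' @param y logit-scale value(s).
#' @param var_y positive logit-scale variance(s).
#' @return a tibble with columns `p` and `var_p`.
#' @export
from_logit <- function(y, var_y) {
  if (any(var_y < 0)) stop("`var_y` must be non-negative.")
  p <- plogis(y)
  tibble::tibble(p = p, var_p = var_y * (p * (1 - p))^2)
}
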