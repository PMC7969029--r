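#' Circular mean of angles in degrees
#'
#' Mean direction of the unit vectors of the input angles, the appropriate
#' average for angular quantities such as backbone torsions or helical twist
#' where 359 degrees and 1 degree are 2 degrees apart, not 358.
#'
#' @param angles numeric vector of angles in degrees (any range).
#' @param tol resultant-length tolerance below which the mean direction is
#'   treated as undefined (e.g. two opposed angles). Default `1e-8`.
#' @return Mean direction in degrees, in (-180, 180].
#' @export
#' @examples
#' circular_mean(c(350, 10))  # 0, not 180
#' circular_mean(c(0, 90))    # 45
circular_mean <- function(angles, tol = 1e-8) {
  if (length(angles) == 0L) {
    ss_stop("circular_mean() requires at least one angle", "empty_input")
  }
  if (!is.numeric(angles) || anyNA(angles)) {
    ss_stop("angles must be numeric and non-missing", "invalid_input")
  }
  rad <- angles * pi / 180
  s <- mean(sin(rad))
  c_ <- mean(cos(rad))
  if (sqrt(s^2 + c_^2) < tol) {
    ss_stop("mean direction undefined: resultant length below tolerance",
            "degenerate_direction")
  }
  deg <- atan2(s, c_) * 180 / pi
  if (deg <= -180) deg <- deg + 360
  deg
}
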