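# Power-vector refraction algebra (M, J0, J45).
#
# Clinical refractions use the negative-cylinder convention throughout:
# cylinder <= 0, axis in degrees in [0, 180), axis stored as 0 when the
# cylinder is zero. Refractions and power vectors travel as data.frames
# so every operation is vectorized over eyes.

#' Construct a refraction table
#'
#' @param sphere sphere S in diopters (vectorized)
#' @param cylinder cylinder C in diopters, negative-cylinder convention
#'   (C <= 0)
#' @param axis cylinder axis in degrees; reduced modulo 180 into [0, 180),
#'   forced to 0 where the cylinder is zero
#' @return data.frame with columns \code{sphere}, \code{cylinder},
#'   \code{axis}
#' @export
refraction <- function(sphere, cylinder = 0, axis = 0) {
  n <- max(length(sphere), length(cylinder), length(axis))
  sphere <- rep_len(as.numeric(sphere), n)
  cylinder <- rep_len(as.numeric(cylinder), n)
  axis <- rep_len(as.numeric(axis), n) %% 180
  if (any(cylinder > 1e-12))
    stop("cylinder must be <= 0 (negative-cylinder convention)")
  cylinder <- pmin(cylinder, 0)
  axis[cylinder == 0] <- 0
  data.frame(sphere = sphere, cylinder = cylinder, axis = axis)
}

#' Convert sphero-cylindrical refractions to power vectors
#'
#' The orthogonal dioptric components are
#' \deqn{M = S + C/2,\quad J0 = -(C/2)\cos 2\alpha,\quad
#'       J45 = -(C/2)\sin 2\alpha.}
#' M is the spherical equivalent; J0 and J45 are the Jackson
#' cross-cylinder components at 0/90 and 45/135 degrees.
#'
#' @param r refraction data.frame (columns \code{sphere}, \code{cylinder},
#'   \code{axis}) as from \code{\link{refraction}}
#' @return data.frame with columns \code{M}, \code{J0}, \code{J45} (D)
#' @examples
#' refractionToPowerVector(refraction(-2, -1, 90))  # M -2.5, J0 -0.5
#' @export
refractionToPowerVector <- function(r) {
  a <- r$axis * pi / 180
  data.frame(M = r$sphere + r$cylinder / 2,
             J0 = -(r$cylinder / 2) * cos(2 * a),
             J45 = -(r$cylinder / 2) * sin(2 * a))
}

#' Convert power vectors back to sphero-cylindrical refractions
#'
#' Inverse of \code{\link{refractionToPowerVector}} onto the
#' negative-cylinder convention:
#' \eqn{C = -2\sqrt{J0^2 + J45^2}}, axis from
#' \eqn{2\alpha = \mathrm{atan2}(J45, J0)} mapped into [0, 180),
#' \eqn{S = M - C/2}. The round trip through
#' \code{refractionToPowerVector} is the identity on valid refractions.
#'
#' @param p data.frame with columns \code{M}, \code{J0}, \code{J45}
#' @return refraction data.frame (\code{sphere}, \code{cylinder},
#'   \code{axis})
#' @export
powerVectorToRefraction <- function(p) {
  cyl <- -2 * sqrt(p$J0^2 + p$J45^2)
  axis <- (atan2(p$J45, p$J0) * 180 / pi / 2) %% 180
  axis[cyl == 0] <- 0
  data.frame(sphere = p$M - cyl / 2, cylinder = cyl, axis = axis)
}

#' Round a refraction to clinical steps under the maximum-plus rule
#'
#' Sphere and cylinder are rounded to the nearest multiple of \code{step};
#' exact midpoints resolve toward the more positive sphere and the
#' smaller-magnitude cylinder (the plus-biased direction for a negative
#' cylinder), emulating the maximum-plus endpoint convention. The axis is
#' rounded to the nearest whole degree.
#'
#' @param r refraction data.frame
#' @param step dioptric step (default 0.25 D)
#' @return rounded refraction data.frame
#' @examples
#' quantizeMaxPlus(refraction(-1.875))$sphere  # -1.75: midpoint toward plus
#' @export
quantizeMaxPlus <- function(r, step = 0.25) {
  if (step <= 0) stop("step must be positive")
  roundPlus <- function(x) floor(x / step + 0.5) * step
  cyl <- pmin(roundPlus(r$cylinder), 0)
  axis <- round(r$axis) %% 180
  axis[cyl == 0] <- 0
  data.frame(sphere = roundPlus(r$sphere), cylinder = cyl, axis = axis)
}
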