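# LD/HD basis construction and coefficient transforms.
#
# The LD/HD ("Low Degree / High Degree") decomposition re-expresses the
# wavefront so that every higher-order mode (radial order n >= 3) contains
# no monomial of total degree <= 2. The low-order modes (n <= 2) are the
# ordinary Zernike modes. Consequence: the low-order LD/HD coefficients
# alone carry the paraxial curvature of the wavefront at the pupil center,
# i.e. the paraxial sphero-cylindrical refraction.

#' Wavefront expansion coefficients
#'
#' A mode-indexed coefficient vector (micrometres) in either the Zernike
#' or the LD/HD basis, together with the pupil radius over which the
#' normalized coordinates are defined.
#'
#' @slot basis \code{"zernike"} or \code{"ldhd"}
#' @slot coeffs named numeric vector, one entry per mode in canonical
#'   ordering (names from \code{\link{modeLabel}}), in micrometres
#' @slot pupilRadius pupil radius in mm (> 0)
#' @slot maxOrder maximum radial order
#' @export
setClass("WavefrontCoefficients",
  representation(basis = "character", coeffs = "numeric",
                 pupilRadius = "numeric", maxOrder = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (!(object@basis %in% c("zernike", "ldhd")))
      msg <- c(msg, "basis must be 'zernike' or 'ldhd'")
    if (length(object@pupilRadius) != 1 || !is.finite(object@pupilRadius) ||
        object@pupilRadius <= 0)
      msg <- c(msg, "pupilRadius must be a single positive number")
    expected <- modeTable(object@maxOrder)$label
    if (length(object@coeffs) != length(expected) ||
        !identical(names(object@coeffs), expected))
      msg <- c(msg, "coeffs must be named by the canonical mode labels")
    if (any(!is.finite(object@coeffs)))
      msg <- c(msg, "coeffs must be finite")
    if (length(msg)) msg else TRUE
  })

#' Construct a WavefrontCoefficients object
#'
#' @param coeffs numeric coefficients (micrometres). Either a full vector in
#'   canonical mode order, or a named vector / list keyed by mode label
#'   (e.g. \code{c(n2_m0 = 1)}); unnamed entries of a short vector are an
#'   error. Missing modes default to zero.
#' @param basis \code{"zernike"} (default) or \code{"ldhd"}
#' @param pupilRadius pupil radius in mm (default 2, i.e. a 4 mm pupil)
#' @param maxOrder maximum radial order (default 6)
#' @return a \code{\linkS4class{WavefrontCoefficients}} object
#' @examples
#' w <- wavefrontCoefficients(c(n2_m0 = 1), pupilRadius = 2)
#' paraxialRefraction(w)  # M = -sqrt(3) D
#' @export
wavefrontCoefficients <- function(coeffs = numeric(0), basis = "zernike",
                                  pupilRadius = 2, maxOrder = 6L) {
  maxOrder <- as.integer(maxOrder)
  labels <- modeTable(maxOrder)$label
  full <- stats::setNames(numeric(length(labels)), labels)
  coeffs <- unlist(coeffs)
  if (length(coeffs)) {
    if (is.null(names(coeffs)) || any(names(coeffs) == "")) {
      if (length(coeffs) != length(labels))
        stop("unnamed coeffs must supply all ", length(labels),
             " modes in canonical order")
      full[] <- coeffs
    } else {
      unknown <- setdiff(names(coeffs), labels)
      if (length(unknown))
        stop("unknown mode label(s): ", paste(unknown, collapse = ", "))
      full[names(coeffs)] <- coeffs
    }
  }
  methods::new("WavefrontCoefficients", basis = basis, coeffs = full,
               pupilRadius = as.numeric(pupilRadius), maxOrder = maxOrder)
}

#' @describeIn wavefrontCoefficients accessor for the coefficient vector
#' @param w a \code{WavefrontCoefficients} object
#' @export
wfCoeffs <- function(w) w@coeffs

#' @describeIn wavefrontCoefficients accessor for the basis tag
#' @export
wfBasis <- function(w) w@basis

#' @describeIn wavefrontCoefficients accessor for the pupil radius (mm)
#' @export
pupilRadius <- function(w) w@pupilRadius

setMethod("show", "WavefrontCoefficients", function(object) {
  nz <- object@coeffs[object@coeffs != 0]
  cat("WavefrontCoefficients [", object@basis, "], max order ",
      object@maxOrder, ", pupil radius ", object@pupilRadius, " mm\n",
      sep = "")
  if (length(nz)) {
    cat("  nonzero modes (um):\n")
    print(round(nz, 6))
  } else cat("  (all coefficients zero)\n")
})

#' Zernike-to-LD/HD change of basis
#'
#' Holds the square coefficient transform between the Zernike and LD/HD
#' representations at a fixed maximum order, plus the exact monomial
#' expansion of each basis set (used for reconstruction, derivatives at
#' the origin, and inner products).
#'
#' @slot maxOrder maximum radial order
#' @slot forward matrix mapping Zernike coefficient vectors to LD/HD
#' @slot inverse its inverse
#' @slot zernikeMono monomial-by-mode matrix of the Zernike basis
#' @slot ldhdMono monomial-by-mode matrix of the LD/HD basis
#' @slot monomials monomial exponent table (columns a, b, degree)
#' @export
setClass("BasisTransform",
  representation(maxOrder = "integer", forward = "matrix",
                 inverse = "matrix", zernikeMono = "matrix",
                 ldhdMono = "matrix", monomials = "data.frame"),
  validity = function(object) {
    k <- modeCount(object@maxOrder)
    if (!all(dim(object@forward) == k) || !all(dim(object@inverse) == k))
      return("transform matrices must be square with one row per mode")
    rt <- object@forward %*% object@inverse
    if (max(abs(rt - diag(k))) > 1e-8)
      return("forward and inverse are not mutual inverses")
    TRUE
  })

setMethod("show", "BasisTransform", function(object) {
  cat("BasisTransform: Zernike <-> LD/HD, max order ", object@maxOrder,
      " (", modeCount(object@maxOrder), " modes)\n", sep = "")
})

.transformCache <- new.env(parent = emptyenv())

#' Build the Zernike-to-LD/HD basis transform
#'
#' Construction: each Zernike mode of radial order >= 3 is expanded in
#' monomials; all terms of total degree <= 2 are deleted; the truncated
#' set is orthonormalized by classical Gram-Schmidt (one re-orthogonalization
#' pass) in canonical mode order under the disk-average inner product, with
#' each mode's sign fixed so it has positive inner product with its parent
#' truncated polynomial. Low-order modes (n <= 2) are kept identical to the
#' Zernike modes. The coefficient transform follows from equating the two
#' monomial expansions, so reconstruction is preserved exactly: the deleted
#' low-degree content of each high-order Zernike mode is absorbed into the
#' low-order LD/HD coefficients.
#'
#' @param maxOrder maximum radial order (>= 3; the standard analysis uses 6)
#' @return a \code{\linkS4class{BasisTransform}}
#' @export
buildLdhdTransform <- function(maxOrder = 6L) {
  maxOrder <- as.integer(maxOrder)
  if (maxOrder < 3L) stop("maxOrder must be >= 3")
  key <- as.character(maxOrder)
  if (!is.null(.transformCache[[key]])) return(.transformCache[[key]])

  mt <- modeTable(maxOrder)
  mono <- monomialTable(maxOrder)
  k <- nrow(mt)
  Q <- monomialGram(mono)          # metric on monomial coordinates
  ip <- function(u, v) as.numeric(crossprod(u, Q %*% v))

  MZ <- sapply(seq_len(k), function(i)
    zernikeMonomials(mt$n[i], mt$m[i], maxOrder))
  dimnames(MZ) <- list(NULL, mt$label)

  MG <- MZ
  low <- mono$degree <= 2
  hi <- which(mt$n >= 3)
  # truncate: remove all degree <= 2 monomial content
  trunc <- MZ[, hi, drop = FALSE]
  trunc[low, ] <- 0
  # classical Gram-Schmidt with one re-orthogonalization pass
  ortho <- trunc
  for (j in seq_along(hi)) {
    v <- ortho[, j]
    for (pass in 1:2) {
      if (j > 1) for (l in seq_len(j - 1))
        v <- v - ip(v, ortho[, l]) * ortho[, l]
    }
    nrm <- sqrt(ip(v, v))
    if (nrm < 1e-10)
      stop("degenerate high-order mode during orthonormalization; ",
           "basis construction failed for order ", maxOrder)
    v <- v / nrm
    if (ip(v, trunc[, j]) < 0) v <- -v
    ortho[, j] <- v
  }
  MG[, hi] <- ortho

  forward <- solve(MG, MZ)         # g = forward %*% c
  condest <- kappa(MG, exact = FALSE)
  if (!is.finite(condest) || condest > 1e10)
    stop("ill-conditioned LD/HD basis matrix (condition ~ ", signif(condest, 3), ")")
  inverse <- solve(forward)
  dimnames(forward) <- list(mt$label, mt$label)
  dimnames(inverse) <- list(mt$label, mt$label)

  out <- methods::new("BasisTransform", maxOrder = maxOrder,
                      forward = forward, inverse = inverse,
                      zernikeMono = MZ, ldhdMono = MG, monomials = mono)
  .transformCache[[key]] <- out
  out
}

.applyTransform <- function(w, t, toBasis) {
  if (!methods::is(w, "WavefrontCoefficients")) stop("w must be WavefrontCoefficients")
  if (w@maxOrder != t@maxOrder)
    stop("transform order (", t@maxOrder, ") does not match coefficients (",
         w@maxOrder, ")")
  mat <- if (toBasis == "ldhd") t@forward else t@inverse
  out <- as.numeric(mat %*% w@coeffs)
  names(out) <- names(w@coeffs)
  methods::new("WavefrontCoefficients", basis = toBasis, coeffs = out,
               pupilRadius = w@pupilRadius, maxOrder = w@maxOrder)
}

#' Convert Zernike coefficients to LD/HD coefficients
#'
#' @param w \code{WavefrontCoefficients} in the Zernike basis
#' @param transform a \code{BasisTransform}; built (and cached) at the
#'   coefficients' order when omitted
#' @return \code{WavefrontCoefficients} in the LD/HD basis describing the
#'   identical wavefront
#' @export
zernikeToLdhd <- function(w, transform = buildLdhdTransform(w@maxOrder)) {
  if (wfBasis(w) != "zernike") stop("input is not in the Zernike basis")
  .applyTransform(w, transform, "ldhd")
}

#' Convert LD/HD coefficients to Zernike coefficients
#' @inheritParams zernikeToLdhd
#' @param w \code{WavefrontCoefficients} in the LD/HD basis
#' @return the same wavefront in the Zernike basis
#' @export
ldhdToZernike <- function(w, transform = buildLdhdTransform(w@maxOrder)) {
  if (wfBasis(w) != "ldhd") stop("input is not in the LD/HD basis")
  .applyTransform(w, transform, "zernike")
}

#' Reconstruct the wavefront height at unit-disk points
#'
#' @param w \code{WavefrontCoefficients} in either basis
#' @param rho unit-disk radius in [0, 1] (vectorized)
#' @param theta angle in radians (vectorized)
#' @param transform optional \code{BasisTransform} (built when omitted)
#' @return wavefront height in micrometres
#' @export
wavefrontEval <- function(w, rho, theta,
                          transform = buildLdhdTransform(w@maxOrder)) {
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  mat <- if (wfBasis(w) == "zernike") transform@zernikeMono else transform@ldhdMono
  monoCoef <- as.numeric(mat %*% w@coeffs)
  x <- rho * cos(theta); y <- rho * sin(theta)
  mono <- transform@monomials
  vals <- numeric(length(x))
  for (i in seq_len(nrow(mono)))
    if (monoCoef[i] != 0)
      vals <- vals + monoCoef[i] * x^mono$a[i] * y^mono$b[i]
  vals
}

#' Paraxial refraction by curvature matching at the pupil center
#'
#' Computes the power vector of the wavefront's paraxial (second-order)
#' curvature at the origin. With W(X, Y) the wavefront in micrometres over
#' physical pupil coordinates in mm, returns
#' \deqn{M = -(W_{XX} + W_{YY})/2,\quad J0 = -(W_{XX} - W_{YY})/2,\quad
#'       J45 = -W_{XY}}
#' evaluated at the pupil center; 1 um/mm^2 reads directly as 1 D. The
#' second derivatives are taken analytically from the exact monomial
#' expansion. This is the reference ("oracle") definition of paraxial
#' matching, valid in either basis; \code{\link{paraxialPredict}} is the
#' closed-form low-order LD/HD shortcut that must agree with it.
#'
#' @param w \code{WavefrontCoefficients} (either basis); coefficients in
#'   micrometres, pupil radius in mm
#' @param transform optional \code{BasisTransform}
#' @return one-row data.frame with columns \code{M}, \code{J0}, \code{J45}
#'   (diopters)
#' @export
paraxialRefraction <- function(w, transform = buildLdhdTransform(w@maxOrder)) {
  if (pupilRadius(w) <= 0) stop("pupilRadius must be positive")
  mat <- if (wfBasis(w) == "zernike") transform@zernikeMono else transform@ldhdMono
  monoCoef <- as.numeric(mat %*% w@coeffs)
  mono <- transform@monomials
  r2 <- pupilRadius(w)^2
  cxx <- monoCoef[mono$a == 2 & mono$b == 0]   # coefficient of x^2
  cyy <- monoCoef[mono$a == 0 & mono$b == 2]   # coefficient of y^2
  cxy <- monoCoef[mono$a == 1 & mono$b == 1]   # coefficient of x y
  Wxx <- 2 * cxx / r2; Wyy <- 2 * cyy / r2; Wxy <- cxy / r2
  data.frame(M = -(Wxx + Wyy) / 2, J0 = -(Wxx - Wyy) / 2, J45 = -Wxy)
}
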