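# Mode indexing ---------------------------------------------------------

#' Zernike / LD-HD mode index table
#'
#' Enumerates the valid double-index pairs (n, m) up to a maximum radial
#' order, in the package's canonical ordering: ascending radial order n,
#' then ascending meridional frequency m. This ordering is used everywhere
#' a coefficient vector or basis matrix is indexed.
#'
#' @param maxOrder maximum radial order (integer >= 0); 6 covers the 28
#'   modes conventionally used for ocular wavefronts.
#' @return a data.frame with columns \code{n}, \code{m} and \code{label}
#'   (e.g. \code{"n4_m-2"}), one row per mode.
#' @examples
#' nrow(modeTable(6))  # 28
#' @export
modeTable <- function(maxOrder = 6L) {
  maxOrder <- as.integer(maxOrder)
  if (is.na(maxOrder) || maxOrder < 0L)
    stop("maxOrder must be a non-negative integer")
  n <- integer(0); m <- integer(0)
  for (ni in 0:maxOrder) {
    mi <- seq(-ni, ni, by = 2L)
    n <- c(n, rep(ni, length(mi)))
    m <- c(m, mi)
  }
  data.frame(n = n, m = m, label = modeLabel(n, m),
             stringsAsFactors = FALSE)
}

#' Canonical label for a mode index
#' @param n radial order(s)
#' @param m meridional frequency(ies)
#' @return character vector like \code{"n2_m0"}, \code{"n4_m-2"}
#' @export
modeLabel <- function(n, m) paste0("n", n, "_m", m)

#' Number of modes up to a radial order
#' @param maxOrder maximum radial order
#' @return \code{(maxOrder + 1)(maxOrder + 2) / 2}
#' @export
modeCount <- function(maxOrder = 6L) ((maxOrder + 1L) * (maxOrder + 2L)) %/% 2L

checkModeIndex <- function(n, m) {
  ok <- is.finite(n) & is.finite(m) & n == round(n) & m == round(m) &
    n >= 0 & abs(m) <= n & (n - abs(m)) %% 2 == 0
  if (!all(ok))
    stop("invalid Zernike mode index (n = ", paste(n[!ok], collapse = ","),
         ", m = ", paste(m[!ok], collapse = ","), ")")
  invisible(TRUE)
}

# Monomial machinery ----------------------------------------------------
#
# Every polynomial on the unit disk is held as a coefficient vector over
# the monomial basis {x^a y^b : a + b <= maxOrder}, ordered by total
# degree then descending power of x. Monomial tables make the inner
# product, the degree-<=2 truncation and derivatives at the origin exact
# (no quadrature enters the basis construction itself).

monomialTable <- function(maxOrder = 6L) {
  a <- integer(0); b <- integer(0)
  for (d in 0:maxOrder) {
    a <- c(a, d:0)
    b <- c(b, 0:d)
  }
  data.frame(a = a, b = b, degree = a + b)
}

# disk-average inner product of x^p y^q over the unit disk:
# (1/pi) * int_disk x^p y^q dx dy, zero unless p and q are both even.
monomialIP <- function(p, q) {
  out <- numeric(length(p))
  even <- p %% 2 == 0 & q %% 2 == 0
  if (any(even)) {
    pp <- p[even]; qq <- q[even]
    out[even] <- 2 * beta((pp + 1) / 2, (qq + 1) / 2) / (pi * (pp + qq + 2))
  }
  out
}

# Gram matrix of the monomial basis under the disk-average inner product
monomialGram <- function(mono) {
  k <- nrow(mono)
  G <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in i:k) {
    v <- monomialIP(mono$a[i] + mono$a[j], mono$b[i] + mono$b[j])
    G[i, j] <- v; G[j, i] <- v
  }
  G
}

# Monomial expansion of one ANSI/OSA-normalized Zernike mode.
# Returns a coefficient vector over monomialTable(maxOrder).
zernikeMonomials <- function(n, m, maxOrder = max(n, 6L)) {
  checkModeIndex(n, m)
  mono <- monomialTable(maxOrder)
  am <- abs(m)
  # radial polynomial R_n^{|m|}: coefficients of rho^(n - 2k)
  radial <- numeric(n + 1)  # index = power of rho + 1
  for (k in 0:((n - am) / 2)) {
    radial[n - 2 * k + 1] <- (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) * factorial((n - am) / 2 - k))
  }
  # azimuthal factor rho^{|m|} cos(|m| theta) (m >= 0) or sin (m < 0),
  # expanded as Re/Im of (x + iy)^{|m|}
  coeffs <- numeric(nrow(mono))
  key <- paste(mono$a, mono$b)
  addMono <- function(a, b, v) {
    i <- match(paste(a, b), key)
    coeffs[i] <<- coeffs[i] + v
  }
  for (p in seq(am, n, by = 2)) {      # powers of rho with nonzero radial coef
    rc <- radial[p + 1]
    if (rc == 0) next
    # rho^p * trig(|m| theta) = (x^2+y^2)^((p-|m|)/2) * [rho^{|m|} trig]
    s <- (p - am) / 2
    for (t in 0:s) {                    # binomial expansion of (x^2+y^2)^s
      w1 <- choose(s, t)                # x^(2(s-t)) y^(2t)
      if (am == 0) {
        addMono(2 * (s - t), 2 * t, rc * w1)
      } else if (m > 0) {
        for (j in seq(0, am, by = 2)) { # Re[(x+iy)^m]
          addMono(am - j + 2 * (s - t), j + 2 * t,
                  rc * w1 * choose(am, j) * (-1)^(j / 2))
        }
      } else {
        for (j in seq(1, am, by = 2)) { # Im[(x+iy)^{|m|}]
          addMono(am - j + 2 * (s - t), j + 2 * t,
                  rc * w1 * choose(am, j) * (-1)^((j - 1) / 2))
        }
      }
    }
  }
  norm <- sqrt(2 * (n + 1) / (1 + as.numeric(m == 0)))
  coeffs * norm
}

#' Evaluate a single Zernike mode on the unit disk
#'
#' ANSI/OSA-normalized Zernike polynomial \eqn{Z_n^m(\rho, \theta)}:
#' the modes are orthonormal under the disk-average inner product
#' \eqn{\langle f, g\rangle = (1/\pi)\int\int_{disk} f g}.
#'
#' @param n radial order
#' @param m meridional frequency (|m| <= n, n - |m| even)
#' @param rho radial coordinate in [0, 1] (vectorized)
#' @param theta angle in radians (vectorized)
#' @return mode value(s), dimensionless
#' @examples
#' zernikeModeEval(2, 0, 1, 0)  # sqrt(3)
#' @export
zernikeModeEval <- function(n, m, rho, theta) {
  checkModeIndex(n, m)
  if (any(rho < 0 | rho > 1)) stop("rho must lie in [0, 1]")
  am <- abs(m)
  radial <- 0
  for (k in 0:((n - am) / 2)) {
    radial <- radial + (-1)^k * factorial(n - k) /
      (factorial(k) * factorial((n + am) / 2 - k) *
         factorial((n - am) / 2 - k)) * rho^(n - 2 * k)
  }
  ang <- if (m > 0) cos(m * theta) else if (m < 0) sin(am * theta) else 1
  sqrt(2 * (n + 1) / (1 + as.numeric(m == 0))) * radial * ang
}
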