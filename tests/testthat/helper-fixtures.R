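# Shared fixtures: everything is built in code at test time.

# the order-6 transform is cached inside the package; grab it once
ldhd6 <- buildLdhdTransform(6L)

# polar quadrature nodes for disk-average integrals:
# (1/pi) int f = sum over nodes of w * f. Gauss-Legendre in rho (exact
# for polynomial radial content) x uniform theta (exact for trigonometric
# polynomials), so polynomial integrands are integrated to round-off.
diskQuadrature <- function(nr = 200, nt = 200) {
  gl <- pracma::gaussLegendre(nr, 0, 1)
  dth <- 2 * pi / nt
  theta <- (seq_len(nt) - 0.5) * dth
  grid <- expand.grid(rho = gl$x, theta = theta)
  grid$w <- rep(gl$w, nt) * grid$rho * dth / pi
  grid
}

# small, fast cohort parameter sets
tinyParams <- function(seed = 7L, ...) {
  cohortParams(nPatients = 30L, seed = seed, ...)
}

# a one-eye cohort with fully controlled Zernike coefficients
singleEyeCohort <- function(zernike, params = cohortParams(nPatients = 1L)) {
  mt <- modeTable(params$maxOrder)
  coeffs <- matrix(0, 1, nrow(mt), dimnames = list(NULL, mt$label))
  coeffs[1, names(zernike)] <- zernike
  eyes <- data.frame(patient_id = "P1", eye_id = "P1_OD", side = "OD",
                     female = TRUE, age = 30, pupil_mm = 5,
                     stringsAsFactors = FALSE)
  methods::new("EyeCohort", eyes = eyes, trueCoeffs = coeffs,
               measuredCoeffs = coeffs, params = unclass(params))
}
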