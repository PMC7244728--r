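# Synthetic eye-cohort generator.
#
# Emulates the statistical structure a wavefront-to-refraction study
# assumes: per-patient refractive demographics with strong inter-eye
# correlation, realistic higher-order aberration magnitudes at a 4 mm
# analysis pupil, and a configurable ground-truth mechanism by which
# higher-order modes shift the subjective endpoint away from the paraxial
# refraction. Everything is seeded and deterministic.

#' Simulated eye cohort
#'
#' Container for a generated (or imported) cohort: one row of \code{eyes}
#' per eye, aligned row-for-row with the true (noise-free) and measured
#' Zernike coefficient matrices.
#'
#' @slot eyes data.frame of per-eye records (ids, demographics, subjective
#'   refraction and its power vector, ground-truth power vectors)
#' @slot trueCoeffs eyes x modes matrix of noise-free Zernike
#'   coefficients (um)
#' @slot measuredCoeffs eyes x modes matrix after instrument noise (um)
#' @slot params the \code{\link{cohortParams}} list used to generate it
#' @export
setClass("EyeCohort",
  representation(eyes = "data.frame", trueCoeffs = "matrix",
                 measuredCoeffs = "matrix", params = "list"),
  validity = function(object) {
    n <- nrow(object@eyes)
    if (nrow(object@trueCoeffs) != n || nrow(object@measuredCoeffs) != n)
      return("coefficient matrices must have one row per eye")
    tab <- table(object@eyes$patient_id)
    if (length(tab) && max(tab) > 2)
      return("at most two eyes per patient")
    dup <- duplicated(object@eyes[c("patient_id", "side")])
    if (any(dup)) return("eye sides must be distinct within a patient")
    TRUE
  })

setMethod("show", "EyeCohort", function(object) {
  cat("EyeCohort: ", nrow(object@eyes), " eyes from ",
      length(unique(object@eyes$patient_id)), " patients\n", sep = "")
  if (nrow(object@eyes)) {
    se <- object@eyes$M
    cat(sprintf("  subjective SE (M): mean %.2f D, SD %.2f D\n",
                mean(se), stats::sd(se)))
  }
})

#' @describeIn EyeCohort per-eye record table
#' @param x an \code{EyeCohort}
#' @export
cohortEyes <- function(x) x@eyes

#' @describeIn EyeCohort noise-free Zernike coefficient matrix (um)
#' @export
trueCoeffs <- function(x) x@trueCoeffs

#' @describeIn EyeCohort measured (noisy) Zernike coefficient matrix (um)
#' @export
measuredCoeffs <- function(x) x@measuredCoeffs

#' @describeIn EyeCohort generation parameters
#' @export
generationParams <- function(x) x@params

#' @describeIn EyeCohort number of eyes
#' @export
nEyes <- function(x) nrow(x@eyes)

#' @describeIn EyeCohort number of distinct patients
#' @export
nPatients <- function(x) length(unique(x@eyes$patient_id))

# truncated-normal moments (closed form)
truncNormMoments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(v))
}

# find (mu, sigma) whose truncated-normal moments on [lo, hi] equal the
# requested observed moments
calibrateTruncNorm <- function(targetMean, targetSd, lo, hi) {
  obj <- function(p) {
    m <- truncNormMoments(p[1], exp(p[2]), lo, hi)
    (m[1] - targetMean)^2 + (m[2] - targetSd)^2
  }
  fit <- stats::optim(c(targetMean, log(targetSd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# quantile function of a truncated normal (exact marginal via copula)
qTruncNorm <- function(u, mu, sigma, lo, hi) {
  pa <- stats::pnorm(lo, mu, sigma); pb <- stats::pnorm(hi, mu, sigma)
  stats::qnorm(pa + u * (pb - pa), mu, sigma)
}

# Zero-inflated truncated normal for the cylinder: point mass at 0 with
# probability p0, otherwise a half-normal-like truncN(0, sigma, [lo, 0]).
# A plain truncated normal bounded above by 0 cannot have SD > |mean|,
# whereas clinic cohorts (many zero-cylinder eyes) do; the point mass
# restores that. Calibrates (p0, sigma) to the target observed moments.
calibrateCylinder <- function(targetMean, targetSd, lo) {
  obj <- function(p) {
    p0 <- stats::plogis(p[1]); sigma <- exp(p[2])
    mm <- truncNormMoments(0, sigma, lo, 0)
    mean <- (1 - p0) * mm[1]
    ex2 <- (1 - p0) * (mm[2]^2 + mm[1]^2)
    sd <- sqrt(max(ex2 - mean^2, 1e-12))
    (mean - targetMean)^2 + (sd - targetSd)^2
  }
  fit <- stats::optim(c(0, log(targetSd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  list(p0 = stats::plogis(fit$par[1]), sigma = exp(fit$par[2]))
}

qCylinder <- function(u, cal, lo) {
  # u ~ U(0,1); upper tail of mass p0 maps to exactly 0
  out <- numeric(length(u))
  inTrunc <- u < (1 - cal$p0)
  if (any(inTrunc))
    out[inTrunc] <- qTruncNorm(u[inTrunc] / (1 - cal$p0), 0, cal$sigma, lo, 0)
  out
}

#' Cohort generation parameters
#'
#' Defaults describe the study conditions the generator emulates: adult
#' refractive-surgery candidates with two eyes per patient, spherical
#' equivalent mean -1.89 D (SD 2.54, range [-6.75, 6.13]), cylinder mean
#' -0.81 D (SD 0.90, bounded above by 0), age mean 36.03 (SD 11.24, range
#' [18, 72]), 57.1% female, strong inter-eye correlation (rho = 0.9) with
#' mirror-symmetric axes, and higher-order aberrations typical of a 4 mm
#' pupil. The mean/SD parameters are the *observed* moments the generated
#' sample should exhibit; the generator calibrates its underlying
#' truncated-normal draws so the post-truncation moments match them.
#'
#' @param nPatients number of patients (two eyes each)
#' @param seed integer seed; every draw in \code{\link{generateCohort}}
#'   descends from it
#' @param seMean,seSd,seBounds observed spherical-equivalent moments (D)
#'   and truncation bounds
#' @param cylMean,cylSd,cylLo observed cylinder moments (D) and lower
#'   bound (upper bound is 0)
#' @param ageMean,ageSd,ageBounds observed age moments (years) and bounds
#' @param fracFemale proportion of female patients
#' @param interEyeRho latent inter-eye correlation for SE and cylinder
#' @param axisMeanDeg,axisSdDeg with-the-rule axis distribution (wrapped
#'   normal around 90 degrees, mirrored between fellow eyes)
#' @param axisJitterDeg per-eye axis jitter (degrees)
#' @param hoaSd3,hoaSd4,hoaSd56 per-mode SDs (um) of the 3rd-, 4th- and
#'   5th/6th-order Zernike coefficients at the analysis pupil
#' @param saMean mean primary spherical aberration c(4,0) in um
#' @param kM,kM6,kJ mechanism weights: dimensionless multipliers on
#'   G(4,0)/r^2 and G(6,0)/r^2 (into M) and G(4,+/-2)/r^2 (into J0/J45);
#'   all zero reduces the subjective endpoint to exact paraxial matching
#' @param noiseSdM,noiseSdJ subjective-refraction noise SDs (D) on M and
#'   on J0/J45, applied before clinical rounding
#' @param coefNoiseSd instrument noise SD per mode (um)
#' @param quantStep clinical rounding step (D); 0 disables rounding
#' @param pupilMean,pupilSd measured pupil diameter distribution (mm);
#'   eyes under 4 mm are excluded by \code{\link{applyExclusions}}
#' @param pupilRadiusMm analysis pupil radius for the coefficients (mm)
#' @param maxOrder maximum radial order of the decomposition
#' @return a validated parameter list of class \code{cohortParams}
#' @export
cohortParams <- function(nPatients = 2281L, seed = 1L,
                         seMean = -1.89, seSd = 2.54,
                         seBounds = c(-6.75, 6.13),
                         cylMean = -0.81, cylSd = 0.90, cylLo = -6,
                         ageMean = 36.03, ageSd = 11.24,
                         ageBounds = c(18, 72),
                         fracFemale = 0.571,
                         interEyeRho = 0.9,
                         axisMeanDeg = 90, axisSdDeg = 25,
                         axisJitterDeg = 5,
                         hoaSd3 = 0.05, hoaSd4 = 0.03, hoaSd56 = 0.015,
                         saMean = 0.02,
                         kM = 2.0, kM6 = -0.5, kJ = 1.5,
                         noiseSdM = 0.12, noiseSdJ = 0.08,
                         coefNoiseSd = 0.01,
                         quantStep = 0.25,
                         pupilMean = 5.0, pupilSd = 0.8,
                         pupilRadiusMm = 2, maxOrder = 6L) {
  p <- list(nPatients = as.integer(nPatients), seed = as.integer(seed),
            seMean = seMean, seSd = seSd, seBounds = seBounds,
            cylMean = cylMean, cylSd = cylSd, cylLo = cylLo,
            ageMean = ageMean, ageSd = ageSd, ageBounds = ageBounds,
            fracFemale = fracFemale, interEyeRho = interEyeRho,
            axisMeanDeg = axisMeanDeg, axisSdDeg = axisSdDeg,
            axisJitterDeg = axisJitterDeg,
            hoaSd3 = hoaSd3, hoaSd4 = hoaSd4, hoaSd56 = hoaSd56,
            saMean = saMean, kM = kM, kM6 = kM6, kJ = kJ,
            noiseSdM = noiseSdM, noiseSdJ = noiseSdJ,
            coefNoiseSd = coefNoiseSd, quantStep = quantStep,
            pupilMean = pupilMean, pupilSd = pupilSd,
            pupilRadiusMm = pupilRadiusMm, maxOrder = as.integer(maxOrder))
  if (p$nPatients < 0) stop("nPatients must be non-negative")
  sds <- c(seSd, cylSd, ageSd, hoaSd3, hoaSd4, hoaSd56,
           noiseSdM, noiseSdJ, coefNoiseSd, pupilSd, axisSdDeg)
  if (any(sds < 0)) stop("standard deviations must be >= 0")
  if (seBounds[1] >= seBounds[2] || ageBounds[1] >= ageBounds[2] ||
      cylLo >= 0)
    stop("truncation bounds must be ordered")
  if (interEyeRho < 0 || interEyeRho > 1)
    stop("interEyeRho must be in [0, 1]")
  if (quantStep < 0) stop("quantStep must be >= 0")
  class(p) <- "cohortParams"
  p
}

# correlated per-eye latent normals: sqrt(rho) shared + sqrt(1-rho) own
.eyePairLatent <- function(nPatients, rho) {
  zp <- stats::rnorm(nPatients)
  ze <- matrix(stats::rnorm(2 * nPatients), nPatients, 2)
  sqrt(rho) * zp + sqrt(1 - rho) * ze
}

#' Generate a seeded synthetic cohort
#'
#' Draws, per patient: age and a spherical equivalent / cylinder pair
#' (exact truncated marginals through a Gaussian copula carrying the
#' inter-eye correlation), mirror-symmetric with-the-rule axes, and per
#' eye the higher-order Zernike coefficients and a measured pupil
#' diameter. The drawn sphero-cylinder is the eye's paraxial refraction;
#' it is converted to the low-order Zernike coefficients at the analysis
#' pupil by inverting the paraxial-matching equations. The subjective
#' ground truth is then formed by \code{\link{trueSubjectiveRefraction}}
#' and observation noise, clinical rounding and instrument noise are added
#' by \code{\link{addNoiseAndQuantize}}.
#'
#' @param params a \code{\link{cohortParams}} list
#' @return an \code{\linkS4class{EyeCohort}}
#' @examples
#' coh <- generateCohort(cohortParams(nPatients = 5, seed = 7))
#' nEyes(coh)
#' @export
generateCohort <- function(params = cohortParams()) {
  if (!inherits(params, "cohortParams")) params <- do.call(cohortParams, params)
  np <- params$nPatients
  mt <- modeTable(params$maxOrder)
  nModes <- nrow(mt)
  if (np == 0) {
    eyes <- emptyEyeFrame()
    return(methods::new("EyeCohort", eyes = eyes,
                        trueCoeffs = matrix(0, 0, nModes,
                                            dimnames = list(NULL, mt$label)),
                        measuredCoeffs = matrix(0, 0, nModes,
                                                dimnames = list(NULL, mt$label)),
                        params = unclass(params)))
  }
  set.seed(params$seed)

  seCal <- calibrateTruncNorm(params$seMean, params$seSd,
                              params$seBounds[1], params$seBounds[2])
  ageCal <- calibrateTruncNorm(params$ageMean, params$ageSd,
                               params$ageBounds[1], params$ageBounds[2])
  cylCal <- calibrateCylinder(params$cylMean, params$cylSd, params$cylLo)

  age <- qTruncNorm(stats::runif(np), ageCal$mu, ageCal$sigma,
                    params$ageBounds[1], params$ageBounds[2])
  female <- stats::runif(np) < params$fracFemale

  zSE <- .eyePairLatent(np, params$interEyeRho)
  se <- matrix(qTruncNorm(stats::pnorm(zSE), seCal$mu, seCal$sigma,
                          params$seBounds[1], params$seBounds[2]), np, 2)
  zCyl <- .eyePairLatent(np, params$interEyeRho)
  cyl <- matrix(qCylinder(stats::pnorm(zCyl), cylCal, params$cylLo), np, 2)

  axBase <- (params$axisMeanDeg +
               stats::rnorm(np, 0, params$axisSdDeg)) %% 180
  axJit <- matrix(stats::rnorm(2 * np, 0, params$axisJitterDeg), np, 2)
  axis <- cbind((axBase + axJit[, 1]) %% 180,         # OD
                (180 - axBase + axJit[, 2]) %% 180)   # OS, mirrored

  nEye <- 2 * np
  patient <- rep(sprintf("P%05d", seq_len(np)), each = 2)
  side <- rep(c("OD", "OS"), np)
  ord <- function(m) t(m)[seq_len(nEye)]   # interleave OD/OS per patient
  seV <- ord(se); cylV <- ord(cyl); axV <- ord(axis)
  axV[cylV == 0] <- 0

  pupil <- stats::rnorm(nEye, params$pupilMean, params$pupilSd)

  # higher-order Zernike coefficients
  coeffs <- matrix(0, nEye, nModes, dimnames = list(NULL, mt$label))
  for (j in seq_len(nModes)) {
    n <- mt$n[j]
    if (n < 3) next
    sd <- if (n == 3) params$hoaSd3 else if (n == 4) params$hoaSd4
          else params$hoaSd56
    coeffs[, j] <- stats::rnorm(nEye, 0, sd)
  }
  coeffs[, "n4_m0"] <- coeffs[, "n4_m0"] + params$saMean

  # Low-order coefficients from the drawn paraxial refraction, inverting
  # the paraxial-matching equations on the LD/HD low-order coefficients.
  # Higher-order Zernike modes absorb low-degree content into G(2, m)
  # (e.g. a unit c(4,0) contributes -sqrt(15) to G(2,0)), so the Zernike
  # c(2, m) are solved for the total G(2, m) to hit the drawn refraction.
  rx <- refraction(seV - cylV / 2, cylV, axV)
  pv <- refractionToPowerVector(rx)
  r2 <- params$pupilRadiusMm^2
  tr <- buildLdhdTransform(params$maxOrder)
  lowLabels <- c("n2_m0", "n2_m2", "n2_m-2")
  absorbed <- coeffs %*% t(tr@forward[lowLabels, , drop = FALSE])
  coeffs[, "n2_m0"] <- -pv$M * r2 / (4 * sqrt(3)) - absorbed[, "n2_m0"]
  coeffs[, "n2_m2"] <- -pv$J0 * r2 / (2 * sqrt(6)) - absorbed[, "n2_m2"]
  coeffs[, "n2_m-2"] <- -pv$J45 * r2 / (2 * sqrt(6)) - absorbed[, "n2_m-2"]

  eyes <- data.frame(
    patient_id = patient,
    eye_id = paste(patient, side, sep = "_"),
    side = side,
    female = rep(female, each = 2),
    age = rep(age, each = 2),
    pupil_mm = pupil,
    stringsAsFactors = FALSE)

  coh <- methods::new("EyeCohort", eyes = eyes, trueCoeffs = coeffs,
                      measuredCoeffs = coeffs, params = unclass(params))

  subjTrue <- trueSubjectiveRefraction(coh)
  coh@eyes$subj_true_M <- subjTrue$M
  coh@eyes$subj_true_J0 <- subjTrue$J0
  coh@eyes$subj_true_J45 <- subjTrue$J45
  addNoiseAndQuantize(coh)
}

emptyEyeFrame <- function() {
  data.frame(patient_id = character(0), eye_id = character(0),
             side = character(0), female = logical(0), age = numeric(0),
             pupil_mm = numeric(0), subj_true_M = numeric(0),
             subj_true_J0 = numeric(0), subj_true_J45 = numeric(0),
             sphere = numeric(0), cylinder = numeric(0), axis = numeric(0),
             M = numeric(0), J0 = numeric(0), J45 = numeric(0),
             stringsAsFactors = FALSE)
}

#' Ground-truth subjective refraction mechanism
#'
#' The subjective endpoint sits between paraxial focus and the wavefront
#' optimum: rotationally matched higher-order LD/HD modes pull the
#' subjective power vector away from the paraxial value,
#' \deqn{M = M_{par} + k_M G_4^0 / r^2 + k_{M6} G_6^0 / r^2,}
#' \deqn{J0 = J0_{par} + k_J G_4^2 / r^2,\quad
#'       J45 = J45_{par} + k_J G_4^{-2} / r^2,}
#' with G in um, r in mm (1 um/mm^2 = 1 D) and dimensionless weights from
#' the cohort parameters. All weights zero reduces exactly to paraxial
#' matching.
#'
#' @param cohort an \code{EyeCohort} with true coefficients populated
#' @param weights list with elements \code{kM}, \code{kM6}, \code{kJ};
#'   defaults taken from the cohort's parameters
#' @return data.frame of per-eye ground-truth \code{M}, \code{J0},
#'   \code{J45} (D)
#' @export
trueSubjectiveRefraction <- function(cohort,
                                     weights = cohort@params[c("kM", "kM6", "kJ")]) {
  p <- cohort@params
  tr <- buildLdhdTransform(p$maxOrder)
  G <- cohort@trueCoeffs %*% t(tr@forward)
  r2 <- p$pupilRadiusMm^2
  data.frame(
    M = -G[, "n2_m0"] * 4 * sqrt(3) / r2 +
      (weights$kM * G[, "n4_m0"] + weights$kM6 * G[, "n6_m0"]) / r2,
    J0 = -G[, "n2_m2"] * 2 * sqrt(6) / r2 + weights$kJ * G[, "n4_m2"] / r2,
    J45 = -G[, "n2_m-2"] * 2 * sqrt(6) / r2 + weights$kJ * G[, "n4_m-2"] / r2,
    row.names = NULL)
}

#' Add observation noise and clinical rounding to a cohort
#'
#' Adds Gaussian noise to each ground-truth subjective power-vector
#' component, converts to sphero-cylinder form, applies plus-biased
#' rounding to the clinical step, and stores the result (and its power
#' vector) as the reported subjective refraction. Instrument noise is
#' added per mode to the measured coefficients in the aberrometer's
#' native reporting basis (LD/HD) and stored as the equivalent Zernike
#' vector.
#'
#' @param cohort an \code{EyeCohort} whose \code{subj_true_*} columns are
#'   populated
#' @param noise list with \code{noiseSdM}, \code{noiseSdJ},
#'   \code{coefNoiseSd} (D, D, um); defaults from the cohort parameters
#' @param quantStep rounding step in D (0 disables); default from the
#'   cohort parameters
#' @param seed optional integer; when supplied, seeds the noise draws so
#'   the operation is reproducible stand-alone
#' @return the cohort with \code{sphere}, \code{cylinder}, \code{axis},
#'   \code{M}, \code{J0}, \code{J45} filled in and noisy
#'   \code{measuredCoeffs}
#' @export
addNoiseAndQuantize <- function(cohort,
                                noise = cohort@params[c("noiseSdM", "noiseSdJ",
                                                        "coefNoiseSd")],
                                quantStep = cohort@params$quantStep,
                                seed = NULL) {
  if (any(unlist(noise) < 0)) stop("noise SDs must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort@eyes)
  if (n == 0) return(cohort)
  pv <- data.frame(
    M = cohort@eyes$subj_true_M + stats::rnorm(n, 0, noise$noiseSdM),
    J0 = cohort@eyes$subj_true_J0 + stats::rnorm(n, 0, noise$noiseSdJ),
    J45 = cohort@eyes$subj_true_J45 + stats::rnorm(n, 0, noise$noiseSdJ))
  rx <- powerVectorToRefraction(pv)
  if (quantStep > 0) rx <- quantizeMaxPlus(rx, quantStep)
  pvOut <- refractionToPowerVector(rx)
  cohort@eyes$sphere <- rx$sphere
  cohort@eyes$cylinder <- rx$cylinder
  cohort@eyes$axis <- rx$axis
  cohort@eyes$M <- pvOut$M
  cohort@eyes$J0 <- pvOut$J0
  cohort@eyes$J45 <- pvOut$J45
  # Instrument noise is applied per reported mode in the device's native
  # output basis (LD/HD), then stored as the equivalent Zernike vector.
  tr <- buildLdhdTransform(cohort@params$maxOrder)
  Gtrue <- cohort@trueCoeffs %*% t(tr@forward)
  Gmeas <- Gtrue + matrix(stats::rnorm(length(Gtrue), 0, noise$coefNoiseSd),
                          nrow = n)
  cohort@measuredCoeffs <- Gmeas %*% t(tr@inverse)
  cohort
}

#' Apply the acquisition pupil exclusion criterion
#'
#' Removes eyes whose measured pupil diameter is below the analysis
#' cut-off (default 4 mm), reporting the counts.
#'
#' @param cohort an \code{EyeCohort}
#' @param minPupilMm exclusion threshold in mm
#' @param verbose print the exclusion accounting
#' @return the filtered cohort
#' @export
applyExclusions <- function(cohort, minPupilMm = 4, verbose = FALSE) {
  keep <- cohort@eyes$pupil_mm >= minPupilMm
  if (verbose)
    message(sum(!keep), " of ", length(keep),
            " eyes excluded (pupil < ", minPupilMm, " mm); ",
            sum(keep), " eyes retained")
  subsetCohort(cohort, keep)
}

subsetCohort <- function(cohort, idx) {
  out <- cohort
  out@eyes <- cohort@eyes[idx, , drop = FALSE]
  rownames(out@eyes) <- NULL
  out@trueCoeffs <- cohort@trueCoeffs[idx, , drop = FALSE]
  out@measuredCoeffs <- cohort@measuredCoeffs[idx, , drop = FALSE]
  out
}

#' Patient-level train/test split
#'
#' Assigns whole patients to the test side by random order until the test
#' eye count first reaches \code{nTestEyes}, so no patient ever
#' contributes eyes to both sides. With paired eyes the test count is
#' \code{nTestEyes} or \code{nTestEyes + 1}.
#'
#' @param cohort an \code{EyeCohort}
#' @param nTestEyes target test-set size in eyes (default 350)
#' @param seed integer seed for the patient permutation
#' @return list with elements \code{train} and \code{test}, both
#'   \code{EyeCohort}s with disjoint patient sets
#' @export
splitCohort <- function(cohort, nTestEyes = 350L, seed = 1L) {
  if (nEyes(cohort) <= nTestEyes)
    stop("cohort has only ", nEyes(cohort), " eyes; cannot hold out ",
         nTestEyes)
  set.seed(seed)
  patients <- unique(cohort@eyes$patient_id)
  perm <- sample(patients)
  counts <- table(cohort@eyes$patient_id)[perm]
  k <- which(cumsum(counts) >= nTestEyes)[1]
  if (is.na(k)) stop("cohort too small for the requested test size")
  testPatients <- perm[seq_len(k)]
  isTest <- cohort@eyes$patient_id %in% testPatients
  list(train = subsetCohort(cohort, !isTest),
       test = subsetCohort(cohort, isTest))
}
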