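test_that("degenerate and deterministic generation contracts hold", {
  empty <- generateCohort(cohortParams(nPatients = 0L))
  expect_equal(nEyes(empty), 0L)

  a <- generateCohort(tinyParams())
  b <- generateCohort(tinyParams())
  expect_equal(cohortEyes(a), cohortEyes(b))
  expect_equal(trueCoeffs(a), trueCoeffs(b))
  expect_equal(measuredCoeffs(a), measuredCoeffs(b))
  # different seed, different cohort
  c <- generateCohort(tinyParams(seed = 8L))
  expect_false(isTRUE(all.equal(cohortEyes(a)$M, cohortEyes(c)$M)))

  # structure: two eyes per patient, distinct sides
  tab <- table(cohortEyes(a)$patient_id)
  expect_true(all(tab == 2))
  expect_error(cohortParams(nPatients = -1), "nPatients")
  expect_error(cohortParams(seSd = -1), "standard deviations")
  expect_error(cohortParams(seBounds = c(2, -2)), "bounds")
})

test_that("marginal refraction and age moments match the target demography", {
  coh <- generateCohort(cohortParams(nPatients = 2000L, seed = 7L))
  e <- cohortEyes(coh)
  # the drawn (paraxial) refraction carries the demographic targets
  G <- trueCoeffs(coh) %*% t(ldhd6@forward)
  pp <- paraxialPredict(G, coh@params$pupilRadiusMm)
  cyl <- -2 * sqrt(pp$J0^2 + pp$J45^2)
  expect_lt(abs(mean(pp$M) - (-1.89)), 0.15)
  expect_lt(abs(sd(pp$M) - 2.54), 0.15)
  expect_lt(abs(mean(cyl) - (-0.81)), 0.12)
  expect_lt(abs(sd(cyl) - 0.90), 0.12)
  expect_lt(abs(mean(e$age) - 36.03), 0.6)
  expect_lt(abs(sd(e$age) - 11.24), 0.6)
  expect_true(all(pp$M >= -6.75 - 1e-9 & pp$M <= 6.13 + 1e-9))
  expect_true(all(cyl <= 0))
  # strong inter-eye correlation of the subjective spherical equivalent
  expect_gt(cor(e$M[e$side == "OD"], e$M[e$side == "OS"]), 0.8)
})

test_that("the subjective mechanism follows its stated linear form", {
  # an eye whose LD/HD spherical aberration is exactly 0.1 um
  g <- setNames(numeric(28), modeTable(6)$label)
  g["n4_m0"] <- 0.1
  cz <- as.numeric(ldhd6@inverse %*% g)
  names(cz) <- modeTable(6)$label
  coh <- singleEyeCohort(cz)
  par <- paraxialRefraction(wavefrontCoefficients(cz, pupilRadius = 2))
  subj <- trueSubjectiveRefraction(coh)
  # k_M * G(4,0) / r^2 = 2 * 0.1 / 4
  expect_equal(subj$M - par$M, 0.05, tolerance = 1e-10)
  expect_equal(subj$J0, par$J0, tolerance = 1e-12)

  # all weights zero reduces to paraxial matching for any eye
  set.seed(9)
  cz2 <- setNames(rnorm(28, 0, 0.1), modeTable(6)$label)
  coh2 <- singleEyeCohort(cz2)
  subj0 <- trueSubjectiveRefraction(coh2,
                                    weights = list(kM = 0, kM6 = 0, kJ = 0))
  par2 <- paraxialRefraction(wavefrontCoefficients(cz2, pupilRadius = 2))
  expect_equal(unlist(subj0), unlist(par2), tolerance = 1e-9)
})

test_that("zero mechanism and zero noise close the loop exactly", {
  p <- cohortParams(nPatients = 50L, seed = 3L, kM = 0, kM6 = 0, kJ = 0,
                    noiseSdM = 0, noiseSdJ = 0, coefNoiseSd = 0,
                    quantStep = 0)
  coh <- generateCohort(p)
  e <- cohortEyes(coh)
  G <- measuredCoeffs(coh) %*% t(ldhd6@forward)
  pp <- paraxialPredict(G, p$pupilRadiusMm)
  expect_lt(max(abs(pp$M - e$M)), 1e-9)
  expect_lt(max(abs(pp$J0 - e$J0)), 1e-9)
  expect_lt(max(abs(pp$J45 - e$J45)), 1e-9)
})

test_that("observation noise plus rounding has the predicted dispersion", {
  # SD of (reported - truth) M over 10^4 eyes: Gaussian noise plus
  # uniform quantization variance, sqrt(0.12^2 + 0.25^2/12)
  coh <- generateCohort(cohortParams(nPatients = 5000L, seed = 31L))
  e <- cohortEyes(coh)
  sdErr <- sd(e$M - e$subj_true_M)
  expect_lt(abs(sdErr / sqrt(0.12^2 + 0.25^2 / 12) - 1), 0.10)
  # with zero noise and an on-grid truth, reporting is exact
  p0 <- cohortParams(nPatients = 20L, seed = 4L, kM = 0, kM6 = 0, kJ = 0,
                     noiseSdM = 0, noiseSdJ = 0, coefNoiseSd = 0)
  e0 <- cohortEyes(generateCohort(p0))
  onGrid <- abs(e0$subj_true_M / 0.25 - round(e0$subj_true_M / 0.25)) < 1e-9
  expect_equal(e0$M[onGrid], e0$subj_true_M[onGrid])
  expect_error(
    addNoiseAndQuantize(generateCohort(tinyParams()),
                        noise = list(noiseSdM = -1, noiseSdJ = 0,
                                     coefNoiseSd = 0)),
    "noise")
})

test_that("pupil exclusion removes the expected fraction", {
  coh <- generateCohort(cohortParams(nPatients = 5000L, seed = 31L))
  kept <- applyExclusions(coh)
  fracExcluded <- 1 - nEyes(kept) / nEyes(coh)
  expect_lt(abs(fracExcluded - pnorm((4 - 5) / 0.8)), 0.01)
  expect_true(all(cohortEyes(kept)$pupil_mm >= 4))
  # boundary behaviours
  expect_equal(nEyes(applyExclusions(coh, minPupilMm = 0)), nEyes(coh))
  expect_equal(nEyes(applyExclusions(coh, minPupilMm = 99)), 0L)
})

test_that("train/test splits are patient-disjoint and size-exact", {
  coh <- generateCohort(cohortParams(nPatients = 300L, seed = 5L))
  sp <- splitCohort(coh, 101L, seed = 1L)
  trainP <- unique(cohortEyes(sp$train)$patient_id)
  testP <- unique(cohortEyes(sp$test)$patient_id)
  expect_length(intersect(trainP, testP), 0L)
  expect_true(nEyes(sp$test) %in% c(101L, 102L))
  expect_equal(nEyes(sp$train) + nEyes(sp$test), nEyes(coh))
  # determinism
  sp2 <- splitCohort(coh, 101L, seed = 1L)
  expect_equal(cohortEyes(sp$test)$eye_id, cohortEyes(sp2$test)$eye_id)
  expect_error(splitCohort(coh, 10000L), "eyes")
})
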