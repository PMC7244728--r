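test_that("paraxial prediction follows the low-order closed form", {
  g <- wavefrontCoefficients(c(n2_m0 = 1), basis = "ldhd", pupilRadius = 2)
  p <- paraxialPredict(g)
  expect_equal(p$M, -sqrt(3), tolerance = 1e-12)
  expect_equal(c(p$J0, p$J45), c(0, 0))
  g2 <- wavefrontCoefficients(c(n2_m2 = -0.5), basis = "ldhd",
                              pupilRadius = 2)
  expect_equal(paraxialPredict(g2)$J0, 0.5 * 2 * sqrt(6) / 4,
               tolerance = 1e-12)
  # high-order-only wavefronts have zero paraxial refraction
  gh <- wavefrontCoefficients(c(n3_m1 = 0.4, n5_m3 = -0.2, n6_m0 = 0.3),
                              basis = "ldhd", pupilRadius = 2)
  expect_equal(unlist(paraxialPredict(gh)), c(M = 0, J0 = 0, J45 = 0))
  # linearity in the coefficients
  gm <- wavefrontCoefficients(c(n2_m0 = 2, n2_m2 = -1), basis = "ldhd",
                              pupilRadius = 2)
  expect_equal(paraxialPredict(gm)$M, 2 * paraxialPredict(g)$M)
  expect_error(paraxialPredict(matrix(0, 1, 1), pupilRadiusMm = -2),
               "pupilRadiusMm")
})

test_that("feature tables have the documented shape and are deterministic", {
  coh <- generateCohort(tinyParams())
  low <- makeFeatureTable(coh, "low_only")
  expect_equal(attr(low, "featureNames"),
               c("G_n2_m-2", "G_n2_m0", "G_n2_m2"))
  all <- makeFeatureTable(coh, "all")
  expect_length(attr(all, "featureNames"), 25L)
  expect_false(any(c("G_n0_m0", "G_n1_m-1", "G_n1_m1") %in%
                     attr(all, "featureNames")))
  withCtl <- makeFeatureTable(coh, "all", addRandomControl = TRUE, seed = 2)
  expect_length(attr(withCtl, "featureNames"), 26L)
  withCtl2 <- makeFeatureTable(coh, "all", addRandomControl = TRUE, seed = 2)
  expect_equal(withCtl, withCtl2)
  # paraxial prediction computed from the table's own low-order features
  # matches the baseline from the raw coefficients (shared plumbing check)
  G <- measuredCoeffs(coh) %*% t(ldhd6@forward)
  expect_equal(unname(as.matrix(low[, c("G_n2_m-2", "G_n2_m0", "G_n2_m2")])),
               unname(G[, c("n2_m-2", "n2_m0", "n2_m2")]))
  # broken coefficients are reported by eye id
  bad <- coh
  bad@measuredCoeffs[2, 3] <- NA_real_
  expect_error(makeFeatureTable(bad, "all"), cohortEyes(coh)$eye_id[2])
})

test_that("tuning is deterministic and learns a noise-free linear target", {
  p <- cohortParams(nPatients = 2150L, seed = 23L, kM = 0, kM6 = 0, kJ = 0,
                    noiseSdM = 0, noiseSdJ = 0, coefNoiseSd = 0,
                    quantStep = 0)
  coh <- generateCohort(p)
  sp <- splitCohort(coh, 300L, seed = 2L)
  tabTr <- makeFeatureTable(sp$train, "low_only")
  tabTe <- makeFeatureTable(sp$test, "low_only")
  spec <- cvSpec(nCandidates = 6L)
  m1 <- tuneAndTrain(tabTr, "M", spec, seed = 3L)
  m2 <- tuneAndTrain(tabTr, "M", spec, seed = 3L)
  expect_equal(m1@bestParams, m2@bestParams)
  expect_equal(predict(m1, tabTe), predict(m2, tabTe))
  # target is exactly linear in G(2,0); n ~ 4000 noise-free rows
  mae <- mean(abs(predict(m1, tabTe) - tabTe$M))
  expect_lt(mae, 0.05)
  # degenerate target refuses to train
  tabC <- tabTr
  tabC$M <- 1.5
  expect_error(tuneAndTrain(tabC, "M", spec), "variance")
  expect_error(tuneAndTrain(tabTr[1:10, ], "M", spec), "50 rows")
})

test_that("prediction is rowwise and column-checked", {
  coh <- generateCohort(cohortParams(nPatients = 60L, seed = 12L))
  tab <- makeFeatureTable(coh, "low_only")
  m <- tuneAndTrain(tab, "J0", cvSpec(nCandidates = 3L), seed = 1L)
  pr <- predict(m, tab)
  expect_length(pr, nrow(tab))
  expect_true(all(is.finite(pr)))
  # empty table, empty prediction
  expect_length(predict(m, tab[0, ]), 0L)
  # permuting rows permutes predictions identically
  idx <- sample(nrow(tab))
  expect_equal(predict(m, tab[idx, ]), pr[idx])
  expect_error(predict(m, tab[, 1:3]), "lacks column")
})

test_that("attributions are additive and rank causal features first", {
  # cohort where only G(2,0) and G(4,0) drive the subjective M
  p <- cohortParams(nPatients = 400L, seed = 17L, kM6 = 0, kJ = 0)
  coh <- generateCohort(p)
  tab <- makeFeatureTable(coh, "all", addRandomControl = TRUE, seed = 5L)
  m <- tuneAndTrain(tab, "M", cvSpec(nCandidates = 5L), seed = 9L)
  fa <- featureAttribution(m, tab)
  # additivity: base + row sums reproduce the prediction (float32 models)
  recon <- fa$baseValue + rowSums(fa$contributions)
  expect_lt(max(abs(recon - predict(m, tab))), 2e-5)
  expect_equal(fa$ranking$feature[1], "G_n2_m0")
  expect_true("random_control" %in% fa$ranking$feature)
  expect_gt(match("random_control", fa$ranking$feature),
            match("G_n4_m0", fa$ranking$feature))
})
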