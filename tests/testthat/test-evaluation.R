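test_that("error computation aligns eyes and preserves sign", {
  coh <- generateCohort(tinyParams())
  e <- cohortEyes(coh)
  perfect <- data.frame(eye_id = rev(e$eye_id), M = rev(e$M),
                        J0 = rev(e$J0), J45 = rev(e$J45))
  err <- computeErrors(perfect, coh)
  expect_equal(max(abs(c(err$M, err$J0, err$J45))), 0)
  shifted <- perfect; shifted$M <- shifted$M + 0.25
  expect_equal(computeErrors(shifted, coh)$M, rep(0.25, nEyes(coh)))
  expect_error(computeErrors(perfect[-1, ], coh), "missing")
})

test_that("summary metrics implement the accuracy/precision definitions", {
  s <- summarizeErrors(c(0.1, -0.1, 0.3))
  expect_equal(s$mae, 1 / 6)
  expect_equal(s$accuracy, 0.1)
  expect_equal(s$sd, 0.2)
  expect_equal(s$precision, 0.4)
  # the published internal relation: SD 0.53 implies precision 1.06
  set.seed(1)
  x <- rnorm(350)
  x <- (x - mean(x)) / sd(x) * 0.53 + 0.06
  s2 <- summarizeErrors(x)
  expect_equal(s2$precision, 1.06, tolerance = 1e-12)
  expect_equal(s2$precision, 2 * s2$sd)
  # MAE dominates |accuracy| for any series
  for (i in 1:20) {
    e <- rnorm(50, rnorm(1), runif(1, 0.01, 1))
    expect_gte(summarizeErrors(e)$mae, abs(summarizeErrors(e)$accuracy))
  }
  expect_error(summarizeErrors(0.1), "at least 2")
})

test_that("pairwise comparisons detect known differences and not identity", {
  set.seed(14)
  a <- rnorm(350, 0, 0.2)
  idSame <- compareMethods(a, a)
  expect_equal(idSame$p_raw, rep(1, 3))
  expect_false(any(idSame$significant))
  # a large location shift is significant after correction
  shifted <- compareMethods(a, a + 0.5, familySize = 3)
  expect_lt(shifted$p_adjusted[shifted$metric == "accuracy"], 0.05)
  # Bonferroni never lowers p and caps at 1
  expect_true(all(shifted$p_adjusted >= shifted$p_raw))
  expect_true(all(idSame$p_adjusted <= 1))
  expect_error(compareMethods(a, a[-1]), "aligned")
})

test_that("the variance comparison has power at a 4x SD ratio", {
  # reference power run: Levene (mean-centered), n = 350 per arm,
  # sigma 0.1 vs 0.4, Bonferroni x3
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    a <- rnorm(350, 0, 0.1); b <- rnorm(350, 0, 0.4)
    cmp <- compareMethods(a, b)
    hits <- hits + (cmp$p_adjusted[cmp$metric == "precision"] < 0.05)
  }
  expect_gte(hits, 95L)
})

test_that("Bland-Altman agreement handles exact, constant and noisy cases", {
  x <- c(1, 2, 3, 4)
  exact <- blandAltman(x, x)
  expect_equal(exact$bias, 0)
  expect_equal(unname(exact$loa), c(0, 0))
  expect_equal(exact$p, 1)
  const <- blandAltman(x + 0.5, x)
  expect_equal(const$bias, 0.5)
  expect_equal(unname(const$loa), c(0.5, 0.5))
  expect_equal(const$p, 0)
  # reference run: zero-centered differences, n = 350, sd 0.2
  set.seed(5)
  d <- rnorm(350, 0, 0.2)
  ba <- blandAltman(d, rep(0, 350))
  expect_lt(abs(ba$bias), 0.04)
  expect_gt(ba$p, 0.05)
  expect_equal(unname(ba$loa["upper"] - ba$loa["lower"]),
               2 * 1.96 * sd(d))
})

test_that("confidence ellipses scale with the sample covariance", {
  set.seed(6)
  j0 <- rnorm(4000, 0, 0.3); j45 <- rnorm(4000, 0, 0.3)
  e <- confidenceEllipse(j0, j45, level = 0.95)
  expect_equal(unname(e$semiAxes),
               rep(0.3 * sqrt(qchisq(0.95, 2)), 2), tolerance = 0.05)
  expect_false(e$degenerate)
  # homogeneity: doubling the errors doubles the axes
  e2 <- confidenceEllipse(2 * j0, 2 * j45)
  expect_equal(e2$semiAxes, 2 * e$semiAxes, tolerance = 1e-9)
  # identical points collapse to a degenerate zero-size ellipse
  e0 <- confidenceEllipse(rep(0.2, 5), rep(-0.1, 5))
  expect_true(e0$degenerate)
  expect_equal(unname(e0$semiAxes), c(0, 0))
  expect_equal(unname(e0$center), c(0.2, -0.1))
})

test_that("the density summary is a unit-mass, shape-faithful estimate", {
  set.seed(8)
  z <- rnorm(400, 0, 0.3)
  sym <- c(z, -z)
  d <- densitySummary(sym)
  expect_gt(d$integral, 0.999)
  expect_lt(d$integral, 1.001)
  # symmetric sample, symmetric density
  expect_lt(max(abs(d$density - rev(d$density))), 0.02 * max(d$density))
  # a narrower sample peaks higher
  dNarrow <- densitySummary(c(z, -z) / 3)
  expect_gt(max(dNarrow$density), max(d$density))
})

test_that("group comparability flags real differences and not null splits", {
  coh <- applyExclusions(generateCohort(cohortParams(nPatients = 400L,
                                                     seed = 13L)))
  sp <- splitCohort(coh, 150L, seed = 1L)
  gc <- groupComparability(sp$train, sp$test)
  expect_equal(gc$variable,
               c("age", "refractive_SE", "refractive_cylinder", "female",
                 "right_eye"))
  expect_true(all(gc$p > 0.05))  # reference null split
  # identical groups compare as identical
  gcSame <- groupComparability(sp$train, sp$train)
  expect_true(all(gcSame$p == 1))
  # a 20-year age shift is unmissable
  shifted <- sp$test
  shifted@eyes$age <- shifted@eyes$age + 20
  expect_lt(groupComparability(sp$train, shifted)$p[1], 0.05)
})

test_that("evaluateMethods assembles a coherent report", {
  coh <- generateCohort(tinyParams(seed = 19L))
  e <- cohortEyes(coh)
  exact <- data.frame(eye_id = e$eye_id, M = e$M, J0 = e$J0, J45 = e$J45)
  biased <- exact
  biased$M <- biased$M + 0.3
  rpt <- evaluateMethods(list(exact = exact, biased = biased), coh)
  s <- reportSummaries(rpt)
  expect_equal(s$mae[s$method == "exact"], rep(0, 3))
  expect_equal(s$mae[s$method == "biased" & s$vector == "M"], 0.3)
  expect_equal(s$precision, 2 * s$sd)
  cmp <- reportComparisons(rpt)
  expect_true(cmp$significant[cmp$vector == "M" & cmp$metric == "accuracy"])
  expect_error(evaluateMethods(list(exact), coh), "named")
})
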