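# Error metrics, pairwise statistical comparisons and agreement analyses
# for refraction prediction methods.
#
# Conventions: the per-eye prediction error is predicted minus subjective
# (D). "Accuracy" is the mean error; "precision" is two times the sample
# (n - 1) standard deviation of the error.

#' Per-eye prediction errors for a set of methods
#'
#' @param predictions data.frame with \code{eye_id} and predicted
#'   \code{M}, \code{J0}, \code{J45} columns
#' @param cohort an \code{EyeCohort} supplying the subjective power
#'   vectors (the reference)
#' @return data.frame with \code{eye_id} and error columns \code{M},
#'   \code{J0}, \code{J45} (predicted - subjective, D)
#' @export
computeErrors <- function(predictions, cohort) {
  eyes <- cohortEyes(cohort)
  idx <- match(eyes$eye_id, predictions$eye_id)
  if (any(is.na(idx)))
    stop("predictions missing for eye(s): ",
         paste(utils::head(eyes$eye_id[is.na(idx)], 5), collapse = ", "))
  data.frame(eye_id = eyes$eye_id,
             M = predictions$M[idx] - eyes$M,
             J0 = predictions$J0[idx] - eyes$J0,
             J45 = predictions$J45[idx] - eyes$J45,
             stringsAsFactors = FALSE)
}

#' Summary metrics of an error series
#'
#' @param errors numeric vector of signed per-eye errors (D), length >= 2
#' @return one-row data.frame: mean absolute error (\code{mae}), mean
#'   error (\code{accuracy}), \code{sd}, \code{precision} (= 2 sd),
#'   \code{min}, \code{max}; absolute-error spread as \code{abs_sd},
#'   \code{abs_min}, \code{abs_max}
#' @export
summarizeErrors <- function(errors) {
  if (length(errors) < 2) stop("need at least 2 errors to summarize")
  s <- stats::sd(errors)
  data.frame(mae = mean(abs(errors)), accuracy = mean(errors), sd = s,
             precision = 2 * s, min = min(errors), max = max(errors),
             abs_sd = stats::sd(abs(errors)), abs_min = min(abs(errors)),
             abs_max = max(abs(errors)))
}

.pairedWilcoxon <- function(x, y) {
  d <- x - y
  if (all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
}

.levene <- function(a, b, center = "mean") {
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) return(1)
  car::leveneTest(y, g, center = center)[1, "Pr(>F)"]
}

#' Pairwise comparison of two methods' error series
#'
#' Paired two-sided Wilcoxon signed-rank tests on the absolute errors
#' (mean-absolute-error comparison) and on the signed errors (accuracy
#' comparison), and a Levene test centered on the mean for the precision
#' (variance) comparison, each with a Bonferroni adjustment over
#' \code{familySize} comparisons. Identical series report p = 1. Zero
#' paired differences are dropped, the signed-rank test's classical
#' handling (recorded in the output).
#'
#' @param a,b aligned numeric error series (same eyes, same order), or
#'   data.frames with \code{eye_id} and an error column named by
#'   \code{vector}
#' @param familySize number of comparisons in the Bonferroni family
#'   (default 3: the method pairs within one vector and one metric)
#' @param vector error column to compare when data.frames are supplied
#' @return data.frame with one row per metric (\code{mae},
#'   \code{accuracy}, \code{precision}): raw p, adjusted p and a 0.05
#'   significance flag on the adjusted p; zero-handling noted in
#'   \code{attr(, "zeroRule")}
#' @export
compareMethods <- function(a, b, familySize = 3L, vector = "M") {
  if (is.data.frame(a)) {
    if (!identical(a$eye_id, b$eye_id))
      stop("error series are not aligned on the same eyes")
    a <- a[[vector]]; b <- b[[vector]]
  }
  if (length(a) != length(b))
    stop("error series are not aligned on the same eyes")
  if (familySize < 1) stop("familySize must be >= 1")
  praw <- c(mae = .pairedWilcoxon(abs(a), abs(b)),
            accuracy = .pairedWilcoxon(a, b),
            precision = .levene(a, b))
  padj <- pmin(1, praw * familySize)
  out <- data.frame(metric = names(praw), p_raw = unname(praw),
                    p_adjusted = unname(padj),
                    significant = unname(padj < 0.05),
                    stringsAsFactors = FALSE)
  attr(out, "zeroRule") <- "zero differences dropped (classical signed-rank)"
  attr(out, "leveneCenter") <- "mean"
  out
}

#' Bland-Altman agreement between predictions and subjective refraction
#'
#' @param predicted,subjective aligned numeric vectors (D), n >= 2
#' @return list: \code{bias} (mean difference), \code{loa} (bias +/- 1.96
#'   SD limits of agreement), \code{sd}, \code{p} from the one-sample t
#'   test of the differences against zero (p = 1 when the differences are
#'   identically zero, 0 when they are a nonzero constant), \code{n}
#' @export
blandAltman <- function(predicted, subjective) {
  if (length(predicted) != length(subjective))
    stop("inputs must be aligned")
  if (length(predicted) < 2) stop("need n >= 2")
  d <- predicted - subjective
  s <- stats::sd(d)
  bias <- mean(d)
  # guard the degenerate case (incl. float round-off of a constant shift)
  if (s <= 1e-12 * max(1, abs(bias))) s <- 0
  p <- if (s == 0) {
    if (bias == 0) 1 else 0
  } else stats::t.test(d)$p.value
  list(bias = bias, loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       sd = s, p = p, n = length(d))
}

#' Bivariate confidence ellipse of (J0, J45) errors
#'
#' Normal-theory ellipse of the bivariate sample: centered at the mean,
#' semi-axes are the square roots of the covariance eigenvalues scaled by
#' the square root of the chi-square(2) quantile at \code{level};
#' orientation is the angle of the leading eigenvector.
#'
#' @param j0Err,j45Err aligned error vectors (D), n >= 3
#' @param level coverage level (default 0.95)
#' @return list: \code{center} (length 2), \code{semiAxes} (major, minor),
#'   \code{orientationDeg}, \code{degenerate} flag for a singular
#'   covariance
#' @export
confidenceEllipse <- function(j0Err, j45Err, level = 0.95) {
  if (length(j0Err) != length(j45Err)) stop("inputs must be aligned")
  if (length(j0Err) < 3) stop("need n >= 3")
  S <- stats::cov(cbind(j0Err, j45Err))
  eig <- eigen(S, symmetric = TRUE)
  degenerate <- eig$values[2] <= .Machine$double.eps * max(eig$values[1], 1)
  q <- stats::qchisq(level, df = 2)
  list(center = c(J0 = mean(j0Err), J45 = mean(j45Err)),
       semiAxes = sqrt(pmax(eig$values, 0) * q),
       orientationDeg = atan2(eig$vectors[2, 1], eig$vectors[1, 1]) * 180 / pi,
       degenerate = degenerate)
}

#' Gaussian kernel density estimate of an error series
#'
#' @param errors numeric vector (D), n >= 2
#' @param n grid size
#' @return list: \code{x} (grid), \code{density}, \code{bandwidth}
#'   (Scott-type rule-of-thumb, recorded), \code{integral} (trapezoid, for
#'   the unit-mass check)
#' @export
densitySummary <- function(errors, n = 512) {
  if (length(errors) < 2) stop("need n >= 2")
  d <- stats::density(errors, bw = "nrd", n = n, cut = 4)
  integral <- sum(diff(d$x) * (utils::head(d$y, -1) + utils::tail(d$y, -1)) / 2)
  list(x = d$x, density = d$y, bandwidth = d$bw, integral = integral)
}

.propTest <- function(k1, n1, k2, n2) {
  if (n1 == 0 || n2 == 0) return(NA_real_)
  if (k1 / n1 == k2 / n2) return(1)
  suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2))$p.value)
}

.tTestP <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) return(1)
  stats::t.test(a, b)$p.value
}

#' Train/test group comparability table
#'
#' Per-group mean/SD/min/max and a two-sample p-value (Welch t-test for
#' continuous variables, proportion test for binary ones) for age,
#' subjective spherical equivalent, cylinder, percent female and percent
#' right eyes.
#'
#' @param train,test \code{EyeCohort}s
#' @return data.frame, one row per variable
#' @export
groupComparability <- function(train, test) {
  et <- cohortEyes(train); ev <- cohortEyes(test)
  contRow <- function(name, a, b) {
    data.frame(variable = name,
               train_mean = mean(a), train_sd = stats::sd(a),
               train_min = min(a), train_max = max(a),
               test_mean = mean(b), test_sd = stats::sd(b),
               test_min = min(b), test_max = max(b),
               p = .tTestP(a, b), stringsAsFactors = FALSE)
  }
  propRow <- function(name, a, b) {
    data.frame(variable = name,
               train_mean = mean(a), train_sd = NA, train_min = NA,
               train_max = NA, test_mean = mean(b), test_sd = NA,
               test_min = NA, test_max = NA,
               p = .propTest(sum(a), length(a), sum(b), length(b)),
               stringsAsFactors = FALSE)
  }
  se <- function(e) e$M  # subjective spherical equivalent
  rbind(contRow("age", et$age, ev$age),
        contRow("refractive_SE", se(et), se(ev)),
        contRow("refractive_cylinder", et$cylinder, ev$cylinder),
        propRow("female", et$female, ev$female),
        propRow("right_eye", et$side == "OD", ev$side == "OD"))
}

#' Evaluation report for a set of prediction methods
#'
#' @slot summaries per-method, per-vector metric grid
#' @slot comparisons pairwise test results
#' @slot blandAltman per-method, per-vector agreement summaries
#' @slot ellipses per-method (J0, J45) ellipse parameters
#' @slot comparability train/test comparability table (may be empty)
#' @slot metadata run options (family size, centering, zero rule, n)
#' @export
setClass("EvaluationReport",
  representation(summaries = "data.frame", comparisons = "data.frame",
                 blandAltman = "data.frame", ellipses = "data.frame",
                 comparability = "data.frame", metadata = "list"))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", object@metadata$nEyes, "test eyes,",
      length(object@metadata$methods), "methods\n")
  cat("\nMean absolute error (D):\n")
  wide <- stats::reshape(object@summaries[, c("method", "vector", "mae")],
                         direction = "wide", idvar = "method",
                         timevar = "vector")
  wide[-1] <- round(wide[-1], 3)
  print(wide, row.names = FALSE)
})

#' @describeIn EvaluationReport metric grid accessor
#' @param x an \code{EvaluationReport}
#' @export
reportSummaries <- function(x) x@summaries

#' @describeIn EvaluationReport pairwise comparison accessor
#' @export
reportComparisons <- function(x) x@comparisons

#' Evaluate prediction methods on a test cohort
#'
#' Computes the full metric grid (MAE, accuracy, SD, precision, min, max)
#' for each method and vector, all pairwise Wilcoxon/Levene comparisons
#' with Bonferroni adjustment over the method pairs within each vector
#' and metric, Bland-Altman agreement, and the (J0, J45) confidence
#' ellipse per method.
#'
#' @param predictions named list of prediction data.frames (each with
#'   \code{eye_id}, \code{M}, \code{J0}, \code{J45})
#' @param cohort the test \code{EyeCohort}
#' @param comparability optional precomputed \code{\link{groupComparability}}
#'   table
#' @return an \code{\linkS4class{EvaluationReport}}
#' @export
evaluateMethods <- function(predictions, cohort, comparability = NULL) {
  if (is.null(names(predictions)) || any(names(predictions) == ""))
    stop("predictions must be a named list of methods")
  methodsN <- names(predictions)
  vectors <- c("M", "J0", "J45")
  errs <- lapply(predictions, computeErrors, cohort = cohort)

  summaries <- do.call(rbind, lapply(methodsN, function(m)
    do.call(rbind, lapply(vectors, function(v)
      cbind(method = m, vector = v, summarizeErrors(errs[[m]][[v]]))))))

  pairs <- if (length(methodsN) > 1) utils::combn(methodsN, 2) else NULL
  familySize <- if (is.null(pairs)) 1L else ncol(pairs)
  comparisons <- if (is.null(pairs)) {
    data.frame()
  } else {
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(i)
      do.call(rbind, lapply(vectors, function(v) {
        cmp <- compareMethods(errs[[pairs[1, i]]], errs[[pairs[2, i]]],
                              familySize = familySize, vector = v)
        cbind(method_a = pairs[1, i], method_b = pairs[2, i], vector = v, cmp)
      }))))
  }

  ba <- do.call(rbind, lapply(methodsN, function(m)
    do.call(rbind, lapply(vectors, function(v) {
      eyes <- cohortEyes(cohort)
      idx <- match(eyes$eye_id, predictions[[m]]$eye_id)
      z <- blandAltman(predictions[[m]][[v]][idx], eyes[[v]])
      data.frame(method = m, vector = v, bias = z$bias,
                 loa_lower = z$loa["lower"], loa_upper = z$loa["upper"],
                 p = z$p, row.names = NULL)
    }))))

  ell <- do.call(rbind, lapply(methodsN, function(m) {
    e <- confidenceEllipse(errs[[m]]$J0, errs[[m]]$J45)
    data.frame(method = m, center_J0 = e$center["J0"],
               center_J45 = e$center["J45"],
               semi_major = e$semiAxes[1], semi_minor = e$semiAxes[2],
               orientation_deg = e$orientationDeg,
               degenerate = e$degenerate, row.names = NULL)
  }))

  methods::new("EvaluationReport", summaries = summaries,
               comparisons = comparisons, blandAltman = ba, ellipses = ell,
               comparability = if (is.null(comparability)) data.frame()
                               else comparability,
               metadata = list(methods = methodsN, nEyes = nEyes(cohort),
                               familySize = familySize,
                               zeroRule = "zero differences dropped",
                               leveneCenter = "mean",
                               sdDefinition = "sample (n-1)"))
}
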