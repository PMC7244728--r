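# End-to-end study pipeline: simulate -> exclude -> decompose -> split ->
# train -> predict -> evaluate, reproducible from one master seed.

# deterministic fan-out of child seeds from the master seed
childSeed <- function(master, k) {
  as.integer((as.numeric(master) %% 100000) * 1009 + 99991 * k) %% 2147483647L
}

#' Study run configuration
#'
#' @param params a \code{\link{cohortParams}}; its seed is overridden by a
#'   child of \code{masterSeed}
#' @param nTestEyes held-out test-set size in eyes (default 350)
#' @param featureSets which predictor variants to train
#' @param cv a \code{\link{cvSpec}} for hyperparameter search
#' @param masterSeed single integer every random stage descends from
#' @param attribution also train control-augmented all-features models and
#'   report their feature attribution rankings
#' @param outDir optional directory for CSV/JSON artifacts
#' @return list of class \code{runConfig}
#' @export
runConfig <- function(params = cohortParams(), nTestEyes = 350L,
                      featureSets = c("low_only", "all"), cv = cvSpec(),
                      masterSeed = 1L, attribution = FALSE, outDir = NULL) {
  stopifnot(all(featureSets %in% c("low_only", "all")))
  out <- list(params = params, nTestEyes = as.integer(nTestEyes),
              featureSets = featureSets, cv = cv,
              masterSeed = as.integer(masterSeed),
              attribution = isTRUE(attribution), outDir = outDir)
  class(out) <- "runConfig"
  out
}

#' Run the full study replica
#'
#' Generates the cohort, applies the pupil exclusion, converts measured
#' coefficients to the LD/HD basis, splits by patient, tunes and trains
#' one gradient-boosted model per requested feature set and power-vector
#' component on the training eyes only, predicts the held-out test eyes,
#' adds the paraxial-matching baseline, and evaluates all methods against
#' the subjective refraction. Test eyes are touched only at prediction
#' time: tuning and training see training rows exclusively.
#'
#' @param config a \code{\link{runConfig}}
#' @param verbose print per-stage row counts
#' @return list with \code{report} (an \code{EvaluationReport}),
#'   \code{predictions} (named list of per-method data.frames),
#'   \code{models} (named list of \code{RefractionModel}s),
#'   \code{sizes} (stage accounting), \code{attribution} (per-vector
#'   rankings when requested) and \code{config}
#' @export
runStudy <- function(config = runConfig(), verbose = FALSE) {
  p <- config$params
  p$seed <- childSeed(config$masterSeed, 1L)
  say <- function(...) if (verbose) message(...)

  cohort <- generateCohort(p)
  say("generated: ", nEyes(cohort), " eyes / ", nPatients(cohort), " patients")
  cohort <- applyExclusions(cohort, verbose = verbose)
  say("after pupil exclusion: ", nEyes(cohort), " eyes")

  halves <- splitCohort(cohort, config$nTestEyes,
                        seed = childSeed(config$masterSeed, 2L))
  train <- halves$train; test <- halves$test
  say("split: ", nEyes(train), " train / ", nEyes(test), " test eyes")

  vectors <- c("M", "J0", "J45")
  models <- list(); predictions <- list()

  # paraxial baseline from the measured LD/HD coefficients of test eyes
  tr <- buildLdhdTransform(p$maxOrder)
  Gtest <- measuredCoeffs(test) %*% t(tr@forward)
  predictions$paraxial <- cbind(
    data.frame(eye_id = cohortEyes(test)$eye_id, stringsAsFactors = FALSE),
    paraxialPredict(Gtest, p$pupilRadiusMm))

  sc <- 10L
  for (fs in config$featureSets) {
    tabTrain <- makeFeatureTable(train, fs)
    tabTest <- makeFeatureTable(test, fs)
    methodName <- if (fs == "all") "xgb_all" else "xgb_low"
    pred <- data.frame(eye_id = cohortEyes(test)$eye_id,
                       stringsAsFactors = FALSE)
    for (v in vectors) {
      sc <- sc + 1L
      m <- tuneAndTrain(tabTrain, v, config$cv,
                        seed = childSeed(config$masterSeed, sc))
      models[[paste(methodName, v, sep = "_")]] <- m
      pred[[v]] <- predict(m, tabTest)
    }
    predictions[[methodName]] <- pred
    say("trained ", methodName, " (", fs, " features)")
  }

  attribution <- NULL
  if (config$attribution) {
    attribution <- list()
    tabTrainC <- makeFeatureTable(train, "all", addRandomControl = TRUE,
                                  seed = childSeed(config$masterSeed, 99L))
    for (v in vectors) {
      sc <- sc + 1L
      m <- tuneAndTrain(tabTrainC, v, config$cv,
                        seed = childSeed(config$masterSeed, sc))
      attribution[[v]] <- featureAttribution(m, tabTrainC)$ranking
    }
  }

  report <- evaluateMethods(predictions, test,
                            comparability = groupComparability(train, test))

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeCohortCsv(cohort, file.path(config$outDir, "cohort.csv"))
    for (m in names(predictions))
      writePredictionsCsv(predictions[[m]],
                          file.path(config$outDir,
                                    paste0("predictions_", m, ".csv")))
    writeReportJson(report, file.path(config$outDir, "report.json"))
    writeLines(c(
      paste("master_seed:", config$masterSeed),
      paste("eyes_generated:", 2L * p$nPatients),
      paste("eyes_after_exclusion:", nEyes(cohort)),
      paste("train_eyes:", nEyes(train)),
      paste("test_eyes:", nEyes(test))),
      file.path(config$outDir, "run_log.txt"))
  }

  list(report = report, predictions = predictions, models = models,
       sizes = list(generated = 2L * p$nPatients,
                    afterExclusion = nEyes(cohort),
                    train = nEyes(train), test = nEyes(test)),
       attribution = attribution, config = config)
}
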