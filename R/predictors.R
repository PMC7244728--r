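# Refraction predictors: closed-form paraxial matching and
# gradient-boosted-tree regression on LD/HD coefficients.

#' Paraxial-matching prediction from LD/HD coefficients
#'
#' Closed-form paraxial refraction from the low-order LD/HD coefficients:
#' \deqn{M = -G_2^0\, 4\sqrt{3} / r^2,\quad J0 = -G_2^2\, 2\sqrt{6} / r^2,
#'       \quad J45 = -G_2^{-2}\, 2\sqrt{6} / r^2}
#' with G in um and the pupil radius r in mm. Because high-order LD/HD
#' modes carry no paraxial content, this equals the curvature of the full
#' wavefront at the pupil center (see \code{\link{paraxialRefraction}},
#' the independent reference computation).
#'
#' @param g either a \code{WavefrontCoefficients} in the LD/HD basis, or a
#'   matrix/data.frame of LD/HD coefficients (um) with columns named by
#'   mode labels (one row per eye)
#' @param pupilRadiusMm pupil radius in mm (taken from the object when
#'   \code{g} is a \code{WavefrontCoefficients})
#' @return data.frame with one row per eye: \code{M}, \code{J0},
#'   \code{J45} in D
#' @export
paraxialPredict <- function(g, pupilRadiusMm = NULL) {
  if (methods::is(g, "WavefrontCoefficients")) {
    if (wfBasis(g) != "ldhd") stop("coefficients must be in the LD/HD basis")
    pupilRadiusMm <- pupilRadius(g)
    g <- matrix(wfCoeffs(g), nrow = 1, dimnames = list(NULL, names(wfCoeffs(g))))
  }
  if (is.null(pupilRadiusMm) || pupilRadiusMm <= 0)
    stop("pupilRadiusMm must be positive")
  g <- as.matrix(g)
  r2 <- pupilRadiusMm^2
  data.frame(M = -g[, "n2_m0"] * 4 * sqrt(3) / r2,
             J0 = -g[, "n2_m2"] * 2 * sqrt(6) / r2,
             J45 = -g[, "n2_m-2"] * 2 * sqrt(6) / r2,
             row.names = NULL)
}

ldhdFeatureNames <- function(maxOrder = 6L, featureSet = c("all", "low_only")) {
  featureSet <- match.arg(featureSet)
  mt <- modeTable(maxOrder)
  if (featureSet == "low_only") {
    mt <- mt[mt$n == 2, ]
  } else {
    mt <- mt[mt$n >= 2, ]          # drop piston, tilt, tip
  }
  paste0("G_", mt$label)
}

#' Build the model feature table for a cohort
#'
#' Features are the measured LD/HD coefficients (um): either all modes of
#' radial order 2 to 6 with piston and both tilts removed (25 features at
#' order 6), or only the low-order trio G(2,0), G(2,2), G(2,-2) (defocus,
#' vertical and oblique astigmatism). Targets are the subjective
#' power-vector components. Optionally appends an i.i.d. standard-normal
#' random control column, used during training to benchmark feature
#' importance against pure noise.
#'
#' @param cohort an \code{EyeCohort} with subjective refraction populated
#' @param featureSet \code{"all"} or \code{"low_only"}
#' @param addRandomControl append the \code{random_control} column
#' @param seed seed for the random control draw
#' @param transform optional \code{BasisTransform}
#' @return data.frame with \code{eye_id}, \code{patient_id}, the feature
#'   columns (prefixed \code{G_}), optionally \code{random_control}, and
#'   targets \code{M}, \code{J0}, \code{J45}; feature names are recorded
#'   in \code{attr(, "featureNames")}, the set tag in
#'   \code{attr(, "featureSet")}
#' @export
makeFeatureTable <- function(cohort, featureSet = c("all", "low_only"),
                             addRandomControl = FALSE, seed = 1L,
                             transform = buildLdhdTransform(cohort@params$maxOrder)) {
  featureSet <- match.arg(featureSet)
  eyes <- cohortEyes(cohort)
  if (nrow(eyes) && any(!is.finite(measuredCoeffs(cohort)))) {
    bad <- eyes$eye_id[apply(!is.finite(measuredCoeffs(cohort)), 1, any)]
    stop("missing or non-finite coefficients for eye(s): ",
         paste(bad, collapse = ", "))
  }
  G <- measuredCoeffs(cohort) %*% t(transform@forward)
  colnames(G) <- paste0("G_", colnames(transform@forward))
  keep <- ldhdFeatureNames(cohort@params$maxOrder, featureSet)
  out <- data.frame(eye_id = eyes$eye_id, patient_id = eyes$patient_id,
                    G[, keep, drop = FALSE],
                    check.names = FALSE, stringsAsFactors = FALSE)
  featNames <- keep
  if (addRandomControl) {
    set.seed(seed)
    out$random_control <- stats::rnorm(nrow(out))
    featNames <- c(featNames, "random_control")
  }
  out$M <- eyes$M; out$J0 <- eyes$J0; out$J45 <- eyes$J45
  attr(out, "featureNames") <- featNames
  attr(out, "featureSet") <- featureSet
  out
}

#' Fitted gradient-boosted-tree refraction predictor
#'
#' @slot target the power-vector component the model predicts
#' @slot featureSet \code{"all"} or \code{"low_only"}
#' @slot featureNames feature columns, in training order
#' @slot booster the fitted xgboost ensemble
#' @slot bestParams chosen hyperparameters (list, includes \code{nrounds})
#' @slot cvSummary data.frame of candidate hyperparameters and CV mean
#'   squared error
#' @slot seed training seed
#' @export
setClass("RefractionModel",
  representation(target = "character", featureSet = "character",
                 featureNames = "character", booster = "ANY",
                 bestParams = "list", cvSummary = "data.frame",
                 seed = "integer"))

setMethod("show", "RefractionModel", function(object) {
  cat("RefractionModel: target ", object@target, ", ",
      length(object@featureNames), " features (", object@featureSet,
      ")\n  best CV MSE ", signif(min(object@cvSummary$cv_mse), 4),
      " over ", nrow(object@cvSummary), " candidates\n", sep = "")
})

#' Randomized-search hyperparameter space and CV layout
#'
#' @param nFolds number of cross-validation folds (folds are grouped by
#'   patient: no patient's eyes are ever split across folds)
#' @param nCandidates randomized-search budget
#' @param nrounds,maxDepth,eta,subsample,colsample,minChildWeight
#'   candidate pools / ranges sampled from
#' @return a list of class \code{cvSpec}
#' @export
cvSpec <- function(nFolds = 5L, nCandidates = 50L,
                   nrounds = c(50L, 100L, 150L, 200L, 300L),
                   maxDepth = 2:6,
                   eta = c(0.03, 0.05, 0.1, 0.2, 0.3),
                   subsample = c(0.6, 1),
                   colsample = c(0.6, 1),
                   minChildWeight = c(1, 3, 5, 10)) {
  out <- list(nFolds = as.integer(nFolds),
              nCandidates = as.integer(nCandidates), nrounds = nrounds,
              maxDepth = maxDepth, eta = eta, subsample = subsample,
              colsample = colsample, minChildWeight = minChildWeight)
  class(out) <- "cvSpec"
  out
}

.sampleCandidates <- function(spec) {
  data.frame(
    nrounds = sample(spec$nrounds, spec$nCandidates, replace = TRUE),
    max_depth = sample(spec$maxDepth, spec$nCandidates, replace = TRUE),
    eta = sample(spec$eta, spec$nCandidates, replace = TRUE),
    subsample = stats::runif(spec$nCandidates, spec$subsample[1],
                             spec$subsample[2]),
    colsample_bytree = stats::runif(spec$nCandidates, spec$colsample[1],
                                    spec$colsample[2]),
    min_child_weight = sample(spec$minChildWeight, spec$nCandidates,
                              replace = TRUE))
}

.xgbFit <- function(X, y, cand, seed) {
  params <- list(max_depth = cand$max_depth, eta = cand$eta,
                 subsample = cand$subsample,
                 colsample_bytree = cand$colsample_bytree,
                 min_child_weight = cand$min_child_weight,
                 objective = "reg:squarederror", nthread = 1,
                 seed = seed)
  xgboost::xgb.train(params = params,
                     data = xgboost::xgb.DMatrix(X, label = y),
                     nrounds = cand$nrounds, verbose = 0)
}

#' Tune and train one power-vector predictor
#'
#' Randomized hyperparameter search with patient-grouped K-fold
#' cross-validation scored by mean squared error, followed by a refit of
#' the best configuration on all rows. Grouping by patient keeps fellow
#' eyes of one patient inside a single fold, matching the patient-level
#' train/test separation of the study design.
#'
#' @param table feature table from \code{\link{makeFeatureTable}}
#' @param target \code{"M"}, \code{"J0"} or \code{"J45"}
#' @param spec a \code{\link{cvSpec}}
#' @param seed integer seed controlling candidate sampling, fold
#'   assignment and the booster's subsampling
#' @return a \code{\linkS4class{RefractionModel}}
#' @export
tuneAndTrain <- function(table, target = c("M", "J0", "J45"),
                         spec = cvSpec(), seed = 1L) {
  target <- match.arg(target)
  if (nrow(table) < 50) stop("need at least 50 rows to tune")
  y <- table[[target]]
  if (stats::sd(y) == 0) stop("target '", target, "' has zero variance")
  featNames <- attr(table, "featureNames")
  X <- as.matrix(table[, featNames, drop = FALSE])

  set.seed(seed)
  cands <- .sampleCandidates(spec)
  patients <- unique(table$patient_id)
  foldOfPatient <- sample(rep_len(seq_len(spec$nFolds), length(patients)))
  fold <- foldOfPatient[match(table$patient_id, patients)]

  cands$cv_mse <- vapply(seq_len(nrow(cands)), function(i) {
    errs <- vapply(seq_len(spec$nFolds), function(k) {
      tr <- fold != k
      if (all(tr) || !any(tr)) return(NA_real_)
      bst <- .xgbFit(X[tr, , drop = FALSE], y[tr], cands[i, ], seed)
      mean((stats::predict(bst, xgboost::xgb.DMatrix(X[!tr, , drop = FALSE])) -
              y[!tr])^2)
    }, numeric(1))
    mean(errs, na.rm = TRUE)
  }, numeric(1))

  best <- cands[which.min(cands$cv_mse), ]
  booster <- .xgbFit(X, y, best, seed)
  methods::new("RefractionModel", target = target,
               featureSet = attr(table, "featureSet"),
               featureNames = featNames, booster = booster,
               bestParams = as.list(best), cvSummary = cands,
               seed = as.integer(seed))
}

.modelMatrix <- function(model, table) {
  missing <- setdiff(model@featureNames, colnames(table))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  as.matrix(table[, model@featureNames, drop = FALSE])
}

#' Predict a power-vector component for a feature table
#'
#' @param object a \code{\linkS4class{RefractionModel}}
#' @param table a feature table containing the model's feature columns
#' @return numeric vector, one prediction (D) per row of \code{table}
#' @export
setMethod("predict", "RefractionModel", function(object, table) {
  if (nrow(table) == 0) return(numeric(0))
  as.numeric(stats::predict(object@booster,
                            xgboost::xgb.DMatrix(.modelMatrix(object, table))))
})

#' Additive per-feature attribution of model predictions
#'
#' Tree-path additive attributions (SHAP values) of each feature towards
#' each prediction: for every row, the base value plus the row's feature
#' contributions reproduces the model output. The global ranking orders
#' features by mean absolute contribution.
#'
#' @param model a fitted \code{\linkS4class{RefractionModel}}
#' @param table feature table to attribute
#' @return list with \code{contributions} (rows x features matrix, D),
#'   \code{baseValue} (D), and \code{ranking} (data.frame of features with
#'   mean absolute contribution, descending)
#' @export
featureAttribution <- function(model, table) {
  X <- .modelMatrix(model, table)
  contrib <- stats::predict(model@booster, xgboost::xgb.DMatrix(X),
                            predcontrib = TRUE)
  biasCol <- intersect(c("BIAS", "(Intercept)"), colnames(contrib))[1]
  base <- contrib[, biasCol]
  contrib <- contrib[, setdiff(colnames(contrib), biasCol), drop = FALSE]
  meanAbs <- colMeans(abs(contrib))
  list(contributions = contrib,
       baseValue = unname(base[1]),
       ranking = data.frame(feature = names(sort(meanAbs, decreasing = TRUE)),
                            mean_abs_contribution =
                              unname(sort(meanAbs, decreasing = TRUE)),
                            stringsAsFactors = FALSE))
}
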