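# Delimited-text interfaces: long-format coefficient tables, cohort
# tables, prediction exports and the change-of-basis matrix dump.

#' Write wavefront coefficients to a long-format CSV
#'
#' One row per mode: \code{eye_id, basis, n, m, value_um, pupil_radius_mm}.
#'
#' @param w a \code{WavefrontCoefficients}, or a named list of them keyed
#'   by eye id
#' @param path output file
#' @param eyeId id used when a single object is given
#' @export
writeWavefrontCsv <- function(w, path, eyeId = "eye1") {
  if (methods::is(w, "WavefrontCoefficients"))
    w <- stats::setNames(list(w), eyeId)
  rows <- do.call(rbind, lapply(names(w), function(id) {
    obj <- w[[id]]
    mt <- modeTable(obj@maxOrder)
    data.frame(eye_id = id, basis = wfBasis(obj), n = mt$n, m = mt$m,
               value_um = unname(wfCoeffs(obj)),
               pupil_radius_mm = pupilRadius(obj),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read wavefront coefficients from a long-format CSV
#'
#' Validates mode indices and pupil radii; missing modes default to zero.
#'
#' @param path CSV written in the \code{\link{writeWavefrontCsv}} layout
#' @param maxOrder maximum radial order of the returned objects
#' @return named list of \code{WavefrontCoefficients}, keyed by eye id
#' @export
readWavefrontCsv <- function(path, maxOrder = 6L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "basis", "n", "m", "value_um", "pupil_radius_mm")
  if (!all(need %in% names(df)))
    stop("coefficient file must have columns: ", paste(need, collapse = ", "))
  checkModeIndex(df$n, df$m)
  if (any(df$pupil_radius_mm <= 0)) stop("pupil_radius_mm must be > 0")
  if (any(df$n > maxOrder))
    stop("file contains modes above order ", maxOrder)
  out <- lapply(split(df, df$eye_id), function(d) {
    if (length(unique(d$basis)) != 1 || length(unique(d$pupil_radius_mm)) != 1)
      stop("eye ", d$eye_id[1], ": basis and pupil radius must be constant")
    wavefrontCoefficients(
      stats::setNames(d$value_um, modeLabel(d$n, d$m)),
      basis = d$basis[1], pupilRadius = d$pupil_radius_mm[1],
      maxOrder = maxOrder)
  })
  out[unique(df$eye_id)]
}

#' Export the Zernike-to-LD/HD matrix for inspection
#'
#' @param transform a \code{BasisTransform}
#' @param path output CSV; rows are LD/HD modes, columns Zernike modes
#' @export
writeTransformCsv <- function(transform, path) {
  utils::write.csv(as.data.frame(transform@forward), path)
  invisible(path)
}

#' Write a cohort's per-eye table to CSV
#' @param cohort an \code{EyeCohort}
#' @param path output file
#' @export
writeCohortCsv <- function(cohort, path) {
  utils::write.csv(cohortEyes(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Write per-eye predictions to CSV
#' @param predictions data.frame with \code{eye_id}, \code{M}, \code{J0},
#'   \code{J45}
#' @param path output file
#' @export
writePredictionsCsv <- function(predictions, path) {
  utils::write.csv(
    data.frame(eye_id = predictions$eye_id, M_hat = predictions$M,
               J0_hat = predictions$J0, J45_hat = predictions$J45),
    path, row.names = FALSE)
  invisible(path)
}

#' Serialize an evaluation report to JSON
#' @param report an \code{EvaluationReport}
#' @param path output file
#' @export
writeReportJson <- function(report, path) {
  jsonlite::write_json(
    list(summaries = report@summaries, comparisons = report@comparisons,
         bland_altman = report@blandAltman, ellipses = report@ellipses,
         comparability = report@comparability, metadata = report@metadata),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
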