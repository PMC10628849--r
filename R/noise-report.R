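#' Full localization-noise diagnostics for a clean/noisy set pair
#'
#' Runs [matchBoxes()] over the shared images, expands the matches into
#' per-boundary errors, and aggregates every noise diagnostic: the scalar
#' noise level \eqn{\gamma} overall and per boundary, mean signed relative
#' errors, \eqn{\sigma}, the size-binned dispersion curve with its
#' through-origin slope, the 4x4 boundary correlation matrix, and per
#' size-class summaries.
#'
#' @param clean,noisy [AnnotationSet-class] objects with overlapping
#'   image_ids (shared images must agree on dimensions).
#' @param bin_width,rescale_to,min_count passed to [binnedSigma()].
#' @return A [NoiseReport-class].
#' @examples
#' truth <- generateAnnotations(40, seed = 1)
#' rep <- noiseReport(truth, synthesizeNoise(truth, gamma = 0.15, seed = 2))
#' gammaOverall(rep)
#' @export
noiseReport <- function(clean, noisy, bin_width = 64, rescale_to = 640,
                        min_count = 10) {
  m <- matchBoxes(clean, noisy)
  pairs <- m$pairs
  if (nrow(pairs) == 0L)
    stop("no clean box could be matched; cannot build a noise report")
  err <- boundaryErrors(pairs)
  perB <- function(f) {
    vapply(.BOUNDARIES, function(bd) {
      f(err[err$boundary == bd, , drop = FALSE])
    }, numeric(1))
  }
  corr <- if (nrow(pairs) >= 3L) boundaryCorrelation(pairs) else
    list(r = matrix(NA_real_, 4, 4, dimnames = list(.BOUNDARIES, .BOUNDARIES)),
         defined = matrix(FALSE, 4, 4,
                          dimnames = list(.BOUNDARIES, .BOUNDARIES)))
  bs <- binnedSigma(err, bin_width = bin_width, rescale_to = rescale_to,
                    min_count = min_count)
  slope <- if (nrow(bs) >= 2L) fitSigmaSlope(bs) else NA_real_
  scs <- do.call(rbind, lapply(c("small", "middle", "large"), function(cl) {
    e <- err[err$size_class == cl, , drop = FALSE]
    data.frame(size_class = cl, n = nrow(e),
               mean_relative = if (nrow(e)) mean(e$relative) else NA_real_,
               sd_relative = if (nrow(e) > 1L) stats::sd(e$relative)
                             else NA_real_,
               stringsAsFactors = FALSE)
  }))
  new("NoiseReport",
      nPairs = nrow(pairs),
      nUnmatchedClean = m$n_unmatched_clean,
      gammaOverall = gammaError(err),
      gammaPerBoundary = perB(gammaError),
      meanRelativePerBoundary = perB(function(e) mean(e$relative)),
      sigmaOverall = sigmaError(err),
      binnedSigma = bs,
      sigmaSlope = slope,
      correlation = corr$r,
      correlationDefined = corr$defined,
      sizeClassStats = scs,
      errors = err)
}

#' @describeIn NoiseReport-class the overall \eqn{\gamma}.
#' @param x A `NoiseReport`.
#' @export
gammaOverall <- function(x) {
  stopifnot(is(x, "NoiseReport"))
  x@gammaOverall
}

#' @describeIn NoiseReport-class the through-origin sigma-size slope.
#' @export
sigmaSlope <- function(x) {
  stopifnot(is(x, "NoiseReport"))
  x@sigmaSlope
}

#' @describeIn NoiseReport-class the long per-boundary error table.
#' @export
reportErrors <- function(x) {
  stopifnot(is(x, "NoiseReport"))
  x@errors
}

setMethod("show", "NoiseReport", function(object) {
  cat("NoiseReport\n")
  cat(sprintf("  pairs: %d matched, %d clean box(es) unmatched\n",
              object@nPairs, object@nUnmatchedClean))
  cat(sprintf("  gamma (RMS relative error): %.4f\n", object@gammaOverall))
  cat("  gamma per boundary:",
      paste(sprintf("%s=%.4f", names(object@gammaPerBoundary),
                    object@gammaPerBoundary), collapse = " "), "\n")
  cat(sprintf("  sigma (RMS absolute error): %.2f px\n", object@sigmaOverall))
  cat(sprintf("  sigma-size slope: %s over %d size bin(s)\n",
              ifelse(is.na(object@sigmaSlope), "NA",
                     sprintf("%.4f", object@sigmaSlope)),
              nrow(object@binnedSigma)))
  und <- sum(!object@correlationDefined[upper.tri(object@correlationDefined)])
  if (und > 0)
    cat(sprintf("  %d off-diagonal correlation(s) undefined\n", und))
})

#' Serialize a NoiseReport to a plain list / JSON file
#'
#' @param x A [NoiseReport-class].
#' @param path optional file; when given, the list is written as JSON.
#' @param histogram_breaks number of breaks for the per-size-class
#'   relative-error histograms included in the serialization.
#' @return Invisibly (when writing) or visibly, the plain-list form.
#' @export
noiseReportToList <- function(x, path = NULL, histogram_breaks = 30) {
  stopifnot(is(x, "NoiseReport"))
  hist_by_class <- lapply(c("small", "middle", "large"), function(cl) {
    e <- x@errors[x@errors$size_class == cl, , drop = FALSE]
    if (nrow(e) == 0L) return(NULL)
    h <- graphics::hist(e$relative, breaks = histogram_breaks, plot = FALSE)
    list(size_class = cl, breaks = h$breaks, counts = h$counts)
  })
  out <- list(
    n_pairs = x@nPairs,
    n_unmatched_clean = x@nUnmatchedClean,
    gamma_overall = x@gammaOverall,
    gamma_per_boundary = as.list(x@gammaPerBoundary),
    mean_relative_per_boundary = as.list(x@meanRelativePerBoundary),
    sigma_overall = x@sigmaOverall,
    binned_sigma = x@binnedSigma,
    sigma_slope = x@sigmaSlope,
    correlation = x@correlation,
    correlation_defined = x@correlationDefined,
    size_class_stats = x@sizeClassStats,
    relative_error_histograms = Filter(Negate(is.null), hist_by_class))
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", matrix = "rowmajor")
    return(invisible(out))
  }
  out
}
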