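#' @import methods
NULL

.BOX_COLS <- c("image_id", "label", "score", "left", "top", "right", "bottom")
.BOUNDARIES <- c("left", "top", "right", "bottom")

#' Empty box table
#'
#' Returns a zero-row data.frame with the canonical box columns
#' (`image_id`, `label`, `score`, `left`, `top`, `right`, `bottom`).
#' Useful for building an [AnnotationSet] with images but no boxes.
#'
#' @return A zero-row data.frame.
#' @export
emptyBoxFrame <- function() {
  data.frame(image_id = character(), label = character(), score = numeric(),
             left = numeric(), top = numeric(), right = numeric(),
             bottom = numeric(), stringsAsFactors = FALSE)
}

.normalizeBoxFrame <- function(boxes) {
  if (is.null(boxes) || nrow(boxes) == 0L) return(emptyBoxFrame())
  if (!"score" %in% names(boxes)) boxes$score <- NA_real_
  boxes <- boxes[, .BOX_COLS, drop = FALSE]
  boxes$image_id <- as.character(boxes$image_id)
  boxes$label <- as.character(boxes$label)
  for (col in c("score", .BOUNDARIES)) boxes[[col]] <- as.numeric(boxes[[col]])
  # canonical order: by image_id, stable within an image
  boxes <- boxes[order(boxes$image_id), , drop = FALSE]
  rownames(boxes) <- NULL
  boxes
}

.normalizeImageFrame <- function(images) {
  stopifnot(is.data.frame(images),
            all(c("image_id", "width", "height") %in% names(images)))
  images <- images[, c("image_id", "width", "height"), drop = FALSE]
  images$image_id <- as.character(images$image_id)
  images$width <- as.numeric(images$width)
  images$height <- as.numeric(images$height)
  images <- images[order(images$image_id), , drop = FALSE]
  rownames(images) <- NULL
  images
}

#' AnnotationSet: a set of bounding-box annotations
#'
#' Container for one annotation set: a table of images (id, width, height)
#' and a table of axis-aligned boxes in continuous 0-based pixel coordinates
#' (edges as real lines, so `width = right - left`). Ground-truth boxes carry
#' `NA` scores; detections/pseudo-labels carry a confidence in \eqn{[0, 1]}.
#'
#' Box coordinates are not required to lie inside the image by validity:
#' noise synthesis and box merging legitimately produce out-of-bounds
#' intermediates. [clipBoxes()] and the VOC writer enforce image bounds.
#'
#' @slot boxes data.frame with columns `image_id`, `label`, `score`,
#'   `left`, `top`, `right`, `bottom`; rows ordered by `image_id` (stable
#'   within an image, which defines the per-image box index used for
#'   alignment in the correction loop).
#' @slot images data.frame with columns `image_id`, `width`, `height`.
#'
#' @seealso [AnnotationSet()], [readVOC()], [writeVOC()]
#' @export
setClass("AnnotationSet",
         representation(boxes = "data.frame", images = "data.frame"))

setValidity("AnnotationSet", function(object) {
  msgs <- character()
  img <- object@images
  b <- object@boxes
  if (!all(c("image_id", "width", "height") %in% names(img)))
    return("images must have columns image_id, width, height")
  if (anyDuplicated(img$image_id))
    msgs <- c(msgs, "duplicated image_id in images")
  if (any(img$width <= 0) || any(img$height <= 0))
    msgs <- c(msgs, "image width and height must be positive")
  if (!all(.BOX_COLS %in% names(b)))
    return(paste("boxes must have columns", paste(.BOX_COLS, collapse = ", ")))
  if (nrow(b) > 0L) {
    if (!all(b$image_id %in% img$image_id))
      msgs <- c(msgs, "boxes reference image_ids absent from images")
    bad <- which(!(b$left < b$right & b$top < b$bottom))
    if (length(bad))
      msgs <- c(msgs, sprintf(
        "degenerate box (left >= right or top >= bottom) at row(s) %s",
        paste(utils::head(bad, 5L), collapse = ", ")))
    s <- b$score
    if (any(!is.na(s) & (s < 0 | s > 1)))
      msgs <- c(msgs, "scores must be in [0, 1] or NA")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotationSet
#'
#' @param boxes data.frame of boxes (see [AnnotationSet-class]); a missing
#'   `score` column is filled with `NA`. May be `NULL`/empty.
#' @param images data.frame with columns `image_id`, `width`, `height`.
#' @return An [AnnotationSet-class] object.
#' @examples
#' img <- data.frame(image_id = "a", width = 640, height = 640)
#' bx <- data.frame(image_id = "a", label = "gray_mold",
#'                  left = 10, top = 20, right = 110, bottom = 220)
#' AnnotationSet(bx, img)
#' @export
AnnotationSet <- function(boxes = emptyBoxFrame(), images) {
  new("AnnotationSet",
      boxes = .normalizeBoxFrame(boxes),
      images = .normalizeImageFrame(images))
}

#' NoiseReport: localization-noise diagnostics
#'
#' Result of [noiseReport()]: matched clean/noisy box pairs summarised as
#' per-boundary errors and the derived noise statistics.
#'
#' @slot nPairs number of matched clean/noisy box pairs.
#' @slot nUnmatchedClean clean boxes with no positive-IoU same-label match.
#' @slot gammaOverall root-mean-square relative boundary error over all
#'   errors (the scalar noise level \eqn{\gamma}).
#' @slot gammaPerBoundary \eqn{\gamma} restricted to each boundary.
#' @slot meanRelativePerBoundary mean signed relative error per boundary.
#' @slot sigmaOverall root-mean-square absolute error (pixels).
#' @slot binnedSigma data.frame of size-binned local dispersion
#'   (`s_bar`, `sigma_local`, `n`), box sizes rescaled to a common image size.
#' @slot sigmaSlope through-origin least-squares slope of `sigma_local`
#'   against `s_bar` (`NA` if fewer than 2 bins survive).
#' @slot correlation 4x4 Pearson correlation matrix of the per-boundary
#'   relative-error series; entries whose series had zero variance are `NA`.
#' @slot correlationDefined logical 4x4 matrix flagging which correlations
#'   were computable (both series non-constant).
#' @slot sizeClassStats per size-class (`small`/`middle`/`large`) count,
#'   mean and standard deviation of the relative errors.
#' @slot errors the long per-boundary error table backing the summaries.
#' @export
setClass("NoiseReport",
         representation(nPairs = "integer",
                        nUnmatchedClean = "integer",
                        gammaOverall = "numeric",
                        gammaPerBoundary = "numeric",
                        meanRelativePerBoundary = "numeric",
                        sigmaOverall = "numeric",
                        binnedSigma = "data.frame",
                        sigmaSlope = "numeric",
                        correlation = "matrix",
                        correlationDefined = "matrix",
                        sizeClassStats = "data.frame",
                        errors = "data.frame"))

setValidity("NoiseReport", function(object) {
  msgs <- character()
  if (length(object@gammaOverall) != 1L || object@gammaOverall < 0)
    msgs <- c(msgs, "gammaOverall must be a single non-negative number")
  if (!identical(dim(object@correlation), c(4L, 4L)))
    msgs <- c(msgs, "correlation must be 4x4")
  bs <- object@binnedSigma
  if (nrow(bs) > 1L && is.unsorted(bs$s_bar))
    msgs <- c(msgs, "binnedSigma must be ordered by s_bar")
  if (length(msgs)) msgs else TRUE
})

#' EvalReport: detection-evaluation summary
#'
#' Result of [evaluateDetections()]: per-class 11-point interpolated average
#' precision at the configured IoU threshold, their unweighted mean
#' (mAP@50 under the defaults), and TP/FP/FN counts at the operating score
#' threshold.
#'
#' @slot perClassAP named numeric vector of AP per ground-truth class
#'   (`NA` where undefined: no truths and no detections).
#' @slot map50 unweighted mean AP over classes with at least one truth box.
#' @slot counts data.frame (`label`, `n_truth`, `tp`, `fp`, `fn`) at the
#'   operating score threshold.
#' @slot iouThreshold IoU threshold used for matching.
#' @slot scoreThreshold operating score threshold used for the counts.
#' @export
setClass("EvalReport",
         representation(perClassAP = "numeric",
                        map50 = "numeric",
                        counts = "data.frame",
                        iouThreshold = "numeric",
                        scoreThreshold = "numeric"))
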