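#' @describeIn AnnotationSet-class the box table.
#' @param x An `AnnotationSet`.
#' @export
annotationBoxes <- function(x) {
  stopifnot(is(x, "AnnotationSet"))
  x@boxes
}

#' @describeIn AnnotationSet-class the image table (`image_id`, `width`,
#'   `height`).
#' @export
imageInfo <- function(x) {
  stopifnot(is(x, "AnnotationSet"))
  x@images
}

#' @describeIn AnnotationSet-class sorted image ids.
#' @export
imageIds <- function(x) imageInfo(x)$image_id

#' @describeIn AnnotationSet-class sorted unique category labels observed.
#' @export
classLabels <- function(x) sort(unique(annotationBoxes(x)$label))

#' @describeIn AnnotationSet-class number of boxes.
#' @export
nBoxes <- function(x) nrow(annotationBoxes(x))

#' @describeIn AnnotationSet-class number of images.
#' @export
nImages <- function(x) nrow(imageInfo(x))

setMethod("show", "AnnotationSet", function(object) {
  b <- object@boxes
  cls <- sort(unique(b$label))
  cat(sprintf("AnnotationSet with %d image(s), %d box(es)\n",
              nrow(object@images), nrow(b)))
  if (length(cls))
    cat("  classes:", paste(utils::head(cls, 8L), collapse = ", "),
        if (length(cls) > 8L) "..." else "", "\n")
  if (nrow(b) && any(!is.na(b$score)))
    cat(sprintf("  scored boxes: %d (score range %.3f-%.3f)\n",
                sum(!is.na(b$score)),
                min(b$score, na.rm = TRUE), max(b$score, na.rm = TRUE)))
})

# dims of the owning image for each box row
.boxImageDims <- function(boxes, images) {
  i <- match(boxes$image_id, images$image_id)
  if (anyNA(i)) stop("boxes reference image_ids absent from images")
  list(width = images$width[i], height = images$height[i])
}

#' Clip boxes to image bounds
#'
#' Clamps every box coordinate into \eqn{[0, W] \times [0, H]} of its owning
#' image. If clamping collapses a box below `minSide` pixels on either side,
#' an error is raised (perturbation callers resample instead, see
#' [synthesizeNoise()]).
#'
#' @param x An [AnnotationSet-class].
#' @param minSide smallest admissible box side after clipping, in pixels.
#' @return An `AnnotationSet` with all boxes inside their images.
#' @export
clipBoxes <- function(x, minSide = 1e-6) {
  stopifnot(is(x, "AnnotationSet"))
  b <- x@boxes
  if (nrow(b) == 0L) return(x)
  d <- .boxImageDims(b, x@images)
  b$left <- pmin(pmax(b$left, 0), d$width)
  b$right <- pmin(pmax(b$right, 0), d$width)
  b$top <- pmin(pmax(b$top, 0), d$height)
  b$bottom <- pmin(pmax(b$bottom, 0), d$height)
  bad <- which(b$right - b$left < minSide | b$bottom - b$top < minSide)
  if (length(bad))
    stop(sprintf("clipping produced degenerate box(es) on image(s): %s",
                 paste(unique(b$image_id[bad]), collapse = ", ")))
  AnnotationSet(b, x@images)
}

# TRUE when the two sets are structurally aligned: same images, and per
# image the same number of boxes with the same labels in the same order.
.checkAligned <- function(a, b, what = "sets") {
  if (!identical(imageIds(a), imageIds(b)))
    stop(sprintf("%s are not aligned: image_ids differ", what))
  ba <- a@boxes; bb <- b@boxes
  if (nrow(ba) != nrow(bb) ||
      !identical(ba$image_id, bb$image_id)) {
    ta <- table(ba$image_id); tb <- table(bb$image_id)
    ids <- union(names(ta), names(tb))
    off <- ids[vapply(ids, function(i) {
      ca <- if (i %in% names(ta)) ta[[i]] else 0L
      cb <- if (i %in% names(tb)) tb[[i]] else 0L
      ca != cb
    }, logical(1))]
    stop(sprintf("%s are not aligned: box-count mismatch on image(s) %s",
                 what, paste(utils::head(off, 5L), collapse = ", ")))
  }
  mis <- which(ba$label != bb$label)
  if (length(mis))
    stop(sprintf("%s are not aligned: label mismatch on image(s) %s",
                 what,
                 paste(unique(utils::head(ba$image_id[mis], 5L)),
                       collapse = ", ")))
  invisible(TRUE)
}

# short numeric fingerprint of a label set, for iteration traces
.setChecksum <- function(x) {
  b <- annotationBoxes(x)
  sprintf("%d:%.4f", nrow(b),
          sum(b$left + b$top + b$right + b$bottom) %% 1e9)
}
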