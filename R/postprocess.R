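#' Filter scored boxes by confidence
#'
#' Keeps boxes with `score >= threshold` (inclusive); within each image the
#' original box order is preserved. Every box must carry a score.
#'
#' @param x a scored [AnnotationSet-class].
#' @param threshold confidence cutoff in \eqn{[0, 1]}.
#' @return An [AnnotationSet-class].
#' @export
filterByScore <- function(x, threshold = 0.5) {
  stopifnot(is(x, "AnnotationSet"), threshold >= 0, threshold <= 1)
  b <- annotationBoxes(x)
  if (nrow(b) && anyNA(b$score))
    stop("filterByScore requires every box to carry a score")
  AnnotationSet(b[which(b$score >= threshold), , drop = FALSE], imageInfo(x))
}

#' Resolve overlapping pseudo-labels
#'
#' Deduplicates boxes that overlap at IoU `>= overlapIoU` within an image.
#' Boxes are swept in descending score order (ties: larger area first, then
#' input order) and accepted greedily. A candidate overlapping an
#' already-accepted box of a *different* category is discarded (the
#' higher-confidence box wins). For overlaps within the *same* category the
#' larger-area box is kept: the candidate replaces the accepted box(es) it
#' overlaps only if it is strictly larger than every one of them, otherwise
#' it is discarded. Surviving boxes are returned in sweep order, so the
#' result does not depend on the input box order.
#'
#' @param x a scored [AnnotationSet-class].
#' @param overlapIoU IoU at or above which two boxes are considered
#'   duplicates (default 0.3).
#' @return An [AnnotationSet-class] with no remaining same-category pair at
#'   or above `overlapIoU`, nor any cross-category pair.
#' @export
resolveOverlaps <- function(x, overlapIoU = 0.3) {
  stopifnot(is(x, "AnnotationSet"), overlapIoU >= 0, overlapIoU <= 1)
  b <- annotationBoxes(x)
  if (nrow(b) && anyNA(b$score))
    stop("resolveOverlaps requires every box to carry a score")
  keep <- lapply(imageIds(x), function(id) {
    bi <- b[b$image_id == id, , drop = FALSE]
    if (nrow(bi) <= 1L) return(bi)
    .resolveImage(bi, overlapIoU)
  })
  AnnotationSet(do.call(rbind, keep), imageInfo(x))
}

.resolveImage <- function(bi, thr) {
  area <- (bi$right - bi$left) * (bi$bottom - bi$top)
  ord <- order(-bi$score, -area) # stable: input order breaks remaining ties
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0L) { accepted <- i; next }
    ious <- boxIoU(bi[accepted, , drop = FALSE], bi[i, , drop = FALSE])
    ov <- accepted[ious >= thr]
    if (length(ov) == 0L) { accepted <- c(accepted, i); next }
    if (any(bi$label[ov] != bi$label[i])) next # confidence rule wins
    if (all(area[i] > area[ov])) { # size rule: strictly larger replaces
      accepted <- c(setdiff(accepted, ov), i)
    } # else: an accepted same-label box is at least as large; discard
  }
  bi[accepted, , drop = FALSE]
}

#' Remove control-class boxes
#'
#' Control categories (background, unknown, healthy by default) absorb
#' false-positive-prone regions during pseudo-labelling and are stripped
#' from the final label set.
#'
#' @param x An [AnnotationSet-class].
#' @param controlLabels character vector of category names to drop.
#' @return An [AnnotationSet-class] without control-class boxes.
#' @export
stripControlClasses <- function(x,
                                controlLabels = c("background", "unknown",
                                                  "healthy")) {
  stopifnot(is(x, "AnnotationSet"))
  b <- annotationBoxes(x)
  AnnotationSet(b[!(b$label %in% controlLabels), , drop = FALSE],
                imageInfo(x))
}

#' Pseudo-label post-processing pipeline
#'
#' Curates a scored pseudo-label set the way an auto-labelling loop needs:
#' low-confidence boxes are dropped ([filterByScore()]), overlapping
#' duplicates are resolved at the IoU threshold ([resolveOverlaps()]), and
#' control-class boxes are stripped ([stripControlClasses()]). The pipeline
#' is idempotent.
#'
#' @param x a scored [AnnotationSet-class].
#' @param scoreThreshold confidence cutoff (default 0.5, inclusive).
#' @param overlapIoU duplicate-overlap threshold (default 0.3).
#' @param controlLabels control categories to strip.
#' @return A curated [AnnotationSet-class].
#' @export
postprocessLabels <- function(x, scoreThreshold = 0.5, overlapIoU = 0.3,
                              controlLabels = c("background", "unknown",
                                                "healthy")) {
  x <- filterByScore(x, scoreThreshold)
  x <- resolveOverlaps(x, overlapIoU)
  stripControlClasses(x, controlLabels)
}
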