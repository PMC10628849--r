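#' Intersection over union of axis-aligned boxes
#'
#' Vectorised over rows/elements: `a` and `b` are either numeric vectors
#' `c(left, top, right, bottom)` or data.frames with those columns (recycled
#' to a common length). Disjoint boxes score 0.
#'
#' @param a,b boxes.
#' @return numeric vector of IoU values in \eqn{[0, 1]}.
#' @export
boxIoU <- function(a, b) {
  ca <- .asCoords(a); cb <- .asCoords(b)
  iw <- pmin(ca$right, cb$right) - pmax(ca$left, cb$left)
  ih <- pmin(ca$bottom, cb$bottom) - pmax(ca$top, cb$top)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  area_a <- (ca$right - ca$left) * (ca$bottom - ca$top)
  area_b <- (cb$right - cb$left) * (cb$bottom - cb$top)
  inter / (area_a + area_b - inter)
}

.asCoords <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(.BOUNDARIES %in% names(x)))
    as.list(x[, .BOUNDARIES])
  } else {
    stopifnot(is.numeric(x), length(x) == 4L)
    list(left = x[1], top = x[2], right = x[3], bottom = x[4])
  }
}

# all-pairs IoU between two box frames (rows of a x rows of b)
.iouMatrix <- function(a, b) {
  m <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b)))
    m[, j] <- boxIoU(a, b[j, , drop = FALSE])
  m
}

#' Match clean boxes to noisy boxes
#'
#' For every clean box, among the noisy boxes of the same image and category
#' with positive IoU, the maximum-IoU one is selected (ties: first in box
#' order). Each clean box yields at most one pair; a noisy box may be reused
#' by several clean boxes (the traversal is per clean box, with no bipartite
#' uniqueness). Clean boxes with no positive-IoU same-label candidate are
#' counted as unmatched and contribute no errors. Images present in only one
#' set are skipped.
#'
#' @param clean,noisy [AnnotationSet-class] objects describing the same
#'   images; shared images must agree on width and height.
#' @return list with `pairs` (data.frame: `image_id`, `label`, `iou`, the
#'   eight clean/noisy coordinates, `image_width`, `image_height`),
#'   `n_unmatched_clean`, and `images_skipped`.
#' @seealso [boundaryErrors()], [noiseReport()]
#' @export
matchBoxes <- function(clean, noisy) {
  stopifnot(is(clean, "AnnotationSet"), is(noisy, "AnnotationSet"))
  ic <- imageInfo(clean); iq <- imageInfo(noisy)
  shared <- intersect(ic$image_id, iq$image_id)
  if (length(shared) == 0L) stop("the two sets share no image_ids")
  dims_c <- ic[match(shared, ic$image_id), ]
  dims_n <- iq[match(shared, iq$image_id), ]
  bad <- which(dims_c$width != dims_n$width | dims_c$height != dims_n$height)
  if (length(bad))
    stop(sprintf("image dimension mismatch on: %s",
                 paste(utils::head(shared[bad], 5L), collapse = ", ")))
  bc <- annotationBoxes(clean); bn <- annotationBoxes(noisy)
  out <- vector("list", length(shared))
  unmatched <- 0L
  for (k in seq_along(shared)) {
    id <- shared[k]
    cc <- bc[bc$image_id == id, , drop = FALSE]
    nn <- bn[bn$image_id == id, , drop = FALSE]
    if (nrow(cc) == 0L) next
    rows <- vector("list", nrow(cc))
    for (i in seq_len(nrow(cc))) {
      cand <- which(nn$label == cc$label[i])
      if (length(cand)) {
        ious <- boxIoU(nn[cand, , drop = FALSE], cc[i, , drop = FALSE])
        keep <- ious > 0
        cand <- cand[keep]; ious <- ious[keep]
      }
      if (length(cand) == 0L) { unmatched <- unmatched + 1L; next }
      j <- cand[which.max(ious)]
      rows[[i]] <- data.frame(
        image_id = id, label = cc$label[i], iou = max(ious),
        clean_left = cc$left[i], clean_top = cc$top[i],
        clean_right = cc$right[i], clean_bottom = cc$bottom[i],
        noisy_left = nn$left[j], noisy_top = nn$top[j],
        noisy_right = nn$right[j], noisy_bottom = nn$bottom[j],
        image_width = dims_c$width[k], image_height = dims_c$height[k],
        stringsAsFactors = FALSE)
    }
    out[[k]] <- do.call(rbind, rows)
  }
  pairs <- do.call(rbind, out)
  if (is.null(pairs)) pairs <- data.frame()
  rownames(pairs) <- NULL
  list(pairs = pairs,
       n_unmatched_clean = unmatched,
       images_skipped = c(setdiff(ic$image_id, shared),
                          setdiff(iq$image_id, shared)))
}

#' Per-boundary errors of matched pairs
#'
#' Expands a pair table from [matchBoxes()] into the long error table: one
#' row per boundary per pair with the signed absolute error
#' \eqn{\Delta = } clean boundary \eqn{-} noisy boundary, the scale
#' \eqn{S} (clean box width for left/right, clean height for top/bottom),
#' the relative error \eqn{\Delta / S}, the owning image dimension, and the
#' size class of \eqn{S} (see [sizeClass()]).
#'
#' @param pairs data.frame as returned in `matchBoxes(...)$pairs`.
#' @return data.frame with columns `image_id`, `boundary`, `delta`, `scale`,
#'   `relative`, `image_dim`, `size_class`.
#' @export
boundaryErrors <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(image_id = character(), boundary = character(),
                      delta = numeric(), scale = numeric(),
                      relative = numeric(), image_dim = numeric(),
                      size_class = character(), stringsAsFactors = FALSE))
  w <- pairs$clean_right - pairs$clean_left
  h <- pairs$clean_bottom - pairs$clean_top
  one <- function(boundary, delta, scale, image_dim)
    data.frame(image_id = pairs$image_id, boundary = boundary,
               delta = delta, scale = scale, relative = delta / scale,
               image_dim = image_dim, stringsAsFactors = FALSE)
  err <- rbind(
    one("left", pairs$clean_left - pairs$noisy_left, w, pairs$image_width),
    one("top", pairs$clean_top - pairs$noisy_top, h, pairs$image_height),
    one("right", pairs$clean_right - pairs$noisy_right, w, pairs$image_width),
    one("bottom", pairs$clean_bottom - pairs$noisy_bottom, h,
        pairs$image_height))
  err$size_class <- sizeClass(err$scale, err$image_dim)
  rownames(err) <- NULL
  err
}

#' Size class of a box side
#'
#' COCO-style relative size classes: a side of length `s` in an image of
#' dimension `imageS` is `small` when \eqn{s/imageS \in (0, 0.1]}, `large`
#' when \eqn{s/imageS \in (0.3, 1]}, `middle` otherwise. Vectorised.
#'
#' @param s box width or height, pixels.
#' @param imageS matching image dimension, pixels.
#' @return character vector in `c("small", "middle", "large")`.
#' @export
sizeClass <- function(s, imageS) {
  if (any(s <= 0) || any(imageS <= 0)) stop("sizes must be positive")
  if (any(s > imageS)) stop("box side exceeds image dimension")
  r <- s / imageS
  ifelse(r <= 0.1, "small", ifelse(r > 0.3, "large", "middle"))
}

#' Root-mean-square relative boundary error (gamma)
#'
#' \eqn{\gamma = \sqrt{\frac{1}{n}\sum_i (\Delta_i / S_i)^2}}, the scalar
#' localization-noise level.
#'
#' @param delta signed absolute errors (pixels), or a long error table from
#'   [boundaryErrors()] (then `scale` is ignored).
#' @param scale per-error scales (pixels).
#' @return a single non-negative number.
#' @export
gammaError <- function(delta, scale = NULL) {
  if (is.data.frame(delta)) { scale <- delta$scale; delta <- delta$delta }
  if (length(delta) == 0L) stop("no boundary errors supplied")
  stopifnot(length(delta) == length(scale), all(scale > 0))
  sqrt(mean((delta / scale)^2))
}

#' Root-mean-square absolute boundary error (sigma)
#'
#' \eqn{\sigma = \sqrt{\frac{1}{n}\sum_i \Delta_i^2}} in pixels.
#'
#' @param delta signed absolute errors (pixels), or a long error table from
#'   [boundaryErrors()].
#' @return a single non-negative number, pixels.
#' @export
sigmaError <- function(delta) {
  if (is.data.frame(delta)) delta <- delta$delta
  if (length(delta) == 0L) stop("no boundary errors supplied")
  sqrt(mean(delta^2))
}

#' Size-binned local error dispersion
#'
#' Rescales every error to a common image size (multiplying both the scale
#' \eqn{S} and the error \eqn{\Delta} by `rescale_to / image_dim`), groups
#' the errors into consecutive `bin_width`-pixel bins of \eqn{S}, and emits
#' one point per sufficiently populated bin: the mean rescaled \eqn{S} and
#' the local \eqn{\sigma} ([sigmaError()]) of the bin.
#'
#' @param errors long error table from [boundaryErrors()].
#' @param bin_width bin width on the rescaled size axis, pixels.
#' @param rescale_to common image size, pixels.
#' @param min_count bins with fewer errors are dropped.
#' @return data.frame (`s_bar`, `sigma_local`, `n`) ordered by `s_bar`.
#' @seealso [fitSigmaSlope()]
#' @export
binnedSigma <- function(errors, bin_width = 64, rescale_to = 640,
                        min_count = 10) {
  stopifnot(nrow(errors) > 0L, bin_width > 0)
  f <- rescale_to / errors$image_dim
  s <- errors$scale * f
  d <- errors$delta * f
  bin <- floor(s / bin_width)
  out <- lapply(sort(unique(bin)), function(bk) {
    i <- which(bin == bk)
    if (length(i) < min_count) return(NULL)
    data.frame(s_bar = mean(s[i]), sigma_local = sigmaError(d[i]),
               n = length(i))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(s_bar = numeric(), sigma_local = numeric(),
                      n = integer())
  res[order(res$s_bar), , drop = FALSE]
}

#' Through-origin slope of the sigma-size relation
#'
#' Least-squares slope of the line \eqn{\sigma_{local} = slope \cdot
#' \bar S} constrained through the origin:
#' \eqn{slope = \sum \bar S \sigma / \sum \bar S^2}. For size-proportional
#' Gaussian noise this slope recovers \eqn{\gamma}.
#'
#' @param points data.frame from [binnedSigma()] (columns `s_bar`,
#'   `sigma_local`).
#' @return the slope, dimensionless.
#' @export
fitSigmaSlope <- function(points) {
  if (nrow(points) < 2L)
    stop("at least 2 binned points are required to fit a slope")
  sum(points$s_bar * points$sigma_local) / sum(points$s_bar^2)
}

#' Pearson correlations between boundary-error series
#'
#' Correlates the four per-boundary relative-error series pairwise across
#' matched pairs. Series with zero variance make a correlation undefined;
#' those entries are returned as `NA` and flagged `FALSE` in `defined`
#' (the diagonal is always 1 / `TRUE`).
#'
#' @param pairs pair table from [matchBoxes()] (at least 3 rows).
#' @return list with `r` (4x4 matrix, dimnames left/top/right/bottom) and
#'   `defined` (logical 4x4).
#' @export
boundaryCorrelation <- function(pairs) {
  if (nrow(pairs) < 3L) stop("at least 3 matched pairs are required")
  w <- pairs$clean_right - pairs$clean_left
  h <- pairs$clean_bottom - pairs$clean_top
  rel <- cbind(left = (pairs$clean_left - pairs$noisy_left) / w,
               top = (pairs$clean_top - pairs$noisy_top) / h,
               right = (pairs$clean_right - pairs$noisy_right) / w,
               bottom = (pairs$clean_bottom - pairs$noisy_bottom) / h)
  sds <- apply(rel, 2, stats::sd)
  r <- matrix(NA_real_, 4, 4, dimnames = list(.BOUNDARIES, .BOUNDARIES))
  defined <- matrix(FALSE, 4, 4, dimnames = list(.BOUNDARIES, .BOUNDARIES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) { r[i, j] <- 1; defined[i, j] <- TRUE; next }
    if (sds[i] > 0 && sds[j] > 0) {
      r[i, j] <- stats::cor(rel[, i], rel[, j])
      defined[i, j] <- TRUE
    }
  }
  list(r = r, defined = defined)
}
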