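.DEFAULT_CLASSES <- c("blossom_end_rot", "gray_mold", "powdery_mildew",
                      "spider_mite", "spotting_disease")

#' Generate a synthetic clean annotation set
#'
#' Produces annotation sets with the statistical structure the noise
#' analysis assumes, with no image data: square images, per-image box counts
#' drawn from a Poisson law (floored at 1), box sides drawn log-uniformly so
#' all three size classes (small/middle/large) are populated, uniform
#' placement inside the image, and labels drawn uniformly from the class
#' list. Single-class configurations (wheat-head-like sets) are supported by
#' passing one class name.
#'
#' @param n_images number of images (0 gives an empty, image-less set).
#' @param image_size square image side, pixels (default 640).
#' @param classes category names (default: five disease-like names).
#' @param boxes_per_image Poisson mean of the per-image box count; each
#'   image gets at least one box.
#' @param size_range `c(min, max)` of the log-uniform box-side law, pixels;
#'   must lie within `(0, image_size]`.
#' @param seed integer seed; generation is fully deterministic under it.
#' @return An [AnnotationSet-class] of unscored boxes.
#' @export
generateAnnotations <- function(n_images, image_size = 640,
                                classes = .DEFAULT_CLASSES,
                                boxes_per_image = 3, size_range = c(16, 480),
                                seed = 1L) {
  stopifnot(n_images >= 0, image_size > 0, length(classes) >= 1,
            boxes_per_image > 0)
  if (size_range[1] <= 0 || size_range[2] > image_size ||
      size_range[1] > size_range[2])
    stop("size_range must lie within (0, image_size]")
  if (n_images == 0L)
    return(AnnotationSet(emptyBoxFrame(),
                         data.frame(image_id = character(), width = numeric(),
                                    height = numeric())))
  ids <- sprintf("img_%05d", seq_len(n_images))
  images <- data.frame(image_id = ids, width = image_size,
                       height = image_size, stringsAsFactors = FALSE)
  .withSeed(seed, {
    counts <- pmax(1L, stats::rpois(n_images, boxes_per_image))
    n <- sum(counts)
    loguni <- function(k) exp(stats::runif(k, log(size_range[1]),
                                           log(size_range[2])))
    w <- loguni(n)
    h <- loguni(n)
    left <- stats::runif(n, 0, image_size - w)
    top <- stats::runif(n, 0, image_size - h)
    boxes <- data.frame(
      image_id = rep(ids, counts),
      label = sample(classes, n, replace = TRUE),
      score = NA_real_,
      left = left, top = top, right = left + w, bottom = top + h,
      stringsAsFactors = FALSE)
    AnnotationSet(boxes, images)
  })
}

#' Generate a synthetic scored detection set
#'
#' Emulates the pseudo-labels a detector would emit for a known ground
#' truth: each truth box is independently dropped with probability
#' `fn_rate` (a missed object), otherwise perturbed at localization noise
#' `loc_gamma` ([synthesizeNoise()] machinery) and given a confidence drawn
#' uniformly from `tp_score_range`. Spurious boxes are then added per image
#' with a Poisson count of mean `fp_rate` times the image's truth-box count,
#' with geometry drawn like [generateAnnotations()] boxes, labels drawn from
#' `fp_classes`, and confidences uniform in `fp_score_range`. The default
#' score laws make a 0.5 confidence cutoff a meaningful filter.
#'
#' @param truths a clean [AnnotationSet-class].
#' @param loc_gamma localization noise level of the kept detections.
#' @param fp_rate expected spurious boxes per truth box, \eqn{\ge 0}.
#' @param fn_rate per-box miss probability in \eqn{[0, 1]}.
#' @param seed integer seed.
#' @param fp_classes labels for spurious boxes (default: the truth classes;
#'   include control labels here to exercise control-class stripping).
#' @param tp_score_range,fp_score_range uniform confidence ranges for kept
#'   and spurious boxes.
#' @param fp_size_range log-uniform side range for spurious boxes, pixels.
#' @return A scored [AnnotationSet-class] over the same images.
#' @export
generateDetections <- function(truths, loc_gamma = 0.1, fp_rate = 0.1,
                               fn_rate = 0.1, seed = 1L,
                               fp_classes = classLabels(truths),
                               tp_score_range = c(0.5, 1),
                               fp_score_range = c(0, 0.7),
                               fp_size_range = c(16, 480)) {
  stopifnot(is(truths, "AnnotationSet"), loc_gamma >= 0, fp_rate >= 0,
            fn_rate >= 0, fn_rate <= 1)
  images <- imageInfo(truths)
  b <- annotationBoxes(truths)
  .withSeed(seed, {
    kept <- if (nrow(b)) b[stats::runif(nrow(b)) >= fn_rate, , drop = FALSE]
            else b
    if (nrow(kept)) {
      d <- .boxImageDims(kept, images)
      kept <- .perturbFrame(kept, d$width, d$height, gamma = loc_gamma,
                            maxResample = 25L, minSide = 1, clip = TRUE)
      kept$score <- stats::runif(nrow(kept), tp_score_range[1],
                                 tp_score_range[2])
    }
    n_truth_per_img <- table(factor(b$image_id, levels = images$image_id))
    n_fp <- stats::rpois(nrow(images), fp_rate * as.integer(n_truth_per_img))
    fp <- NULL
    if (sum(n_fp) > 0 && length(fp_classes)) {
      m <- sum(n_fp)
      img_idx <- rep(seq_len(nrow(images)), n_fp)
      side_max <- pmin(fp_size_range[2],
                       pmin(images$width, images$height)[img_idx])
      loguni <- function(lo, hi) exp(stats::runif(m, log(lo), log(hi)))
      w <- loguni(fp_size_range[1], side_max)
      h <- loguni(fp_size_range[1], side_max)
      left <- stats::runif(m, 0, images$width[img_idx] - w)
      top <- stats::runif(m, 0, images$height[img_idx] - h)
      fp <- data.frame(
        image_id = images$image_id[img_idx],
        label = sample(fp_classes, m, replace = TRUE),
        score = stats::runif(m, fp_score_range[1], fp_score_range[2]),
        left = left, top = top, right = left + w, bottom = top + h,
        stringsAsFactors = FALSE)
    }
    AnnotationSet(rbind(kept, fp), images)
  })
}
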