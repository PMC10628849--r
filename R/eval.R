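#' 11-point interpolated average precision for one class
#'
#' Detections are ranked by descending score (ties: input order). Each
#' detection greedily matches the highest-IoU not-yet-matched truth box of
#' its image with IoU at or above `iou_threshold` (a true positive);
#' otherwise it is a false positive. Precision and recall are accumulated
#' down the ranking and AP is the mean, over the 11 recall levels
#' \eqn{r \in \{0, 0.1, \ldots, 1\}}, of the interpolated precision
#' \eqn{P(r) = \max_{\tilde r \ge r} p(\tilde r)} (0 where the recall level
#' is never reached).
#'
#' @param detections data.frame of scored boxes of one class (columns
#'   `image_id`, `score`, `left`, `top`, `right`, `bottom`).
#' @param truths data.frame of ground-truth boxes of that class (same
#'   columns, scores ignored).
#' @param iou_threshold IoU at or above which a detection can claim a truth.
#' @return list with `ap` (numeric, `NA` when both inputs are empty),
#'   `defined` (FALSE only in that empty/empty case), `n_truth`, and the
#'   per-rank `tp` logical vector.
#' @seealso [evaluateDetections()]
#' @export
ap11point <- function(detections, truths, iou_threshold = 0.5) {
  nd <- NROW(detections); nt <- NROW(truths)
  if (nt == 0L && nd == 0L)
    return(list(ap = NA_real_, defined = FALSE, n_truth = 0L, tp = logical()))
  if (nt == 0L) {
    warning("detections present but no ground truth for this class; AP = 0")
    return(list(ap = 0, defined = TRUE, n_truth = 0L, tp = rep(FALSE, nd)))
  }
  if (nd == 0L)
    return(list(ap = 0, defined = TRUE, n_truth = nt, tp = logical()))
  if (anyNA(detections$score)) stop("detections must be scored")
  ord <- order(-detections$score) # stable; ties keep input order
  det <- detections[ord, , drop = FALSE]
  tp <- .greedyTP(det, truths, iou_threshold)
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / nt
  precision <- cum_tp / (cum_tp + cum_fp)
  ap <- mean(vapply(seq(0, 1, by = 0.1), function(r) {
    p <- precision[recall >= r]
    if (length(p)) max(p) else 0
  }, numeric(1)))
  list(ap = ap, defined = TRUE, n_truth = nt, tp = tp)
}

# greedy VOC-style TP assignment for score-ordered detections
.greedyTP <- function(det, truths, thr) {
  used <- rep(FALSE, nrow(truths))
  tp <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(det))) {
    cand <- which(truths$image_id == det$image_id[i] & !used)
    if (length(cand) == 0L) next
    ious <- boxIoU(truths[cand, , drop = FALSE], det[i, , drop = FALSE])
    j <- which.max(ious)
    if (ious[j] >= thr) {
      tp[i] <- TRUE
      used[cand[j]] <- TRUE
    }
  }
  tp
}

#' Evaluate detections against ground truth (mAP@50)
#'
#' Computes the per-class 11-point AP ([ap11point()]) at the IoU threshold
#' over every class present in the ground truth, and their unweighted mean
#' (mAP@50 at the default threshold 0.5). Detection classes absent from the
#' ground truth are excluded from the mean. TP/FP/FN counts are reported at
#' the operating score threshold.
#'
#' @param detections a scored [AnnotationSet-class].
#' @param truths the ground-truth [AnnotationSet-class].
#' @param iou_threshold IoU threshold for matching (default 0.5).
#' @param score_threshold operating point for the TP/FP/FN counts
#'   (default 0.5; does not affect AP, which sweeps all scores).
#' @return An [EvalReport-class].
#' @examples
#' truth <- generateAnnotations(20, seed = 1)
#' det <- generateDetections(truth, loc_gamma = 0.05, seed = 2)
#' evaluateDetections(det, truth)
#' @export
evaluateDetections <- function(detections, truths, iou_threshold = 0.5,
                               score_threshold = 0.5) {
  stopifnot(is(detections, "AnnotationSet"), is(truths, "AnnotationSet"))
  bd <- annotationBoxes(detections)
  bt <- annotationBoxes(truths)
  if (nrow(bd) && anyNA(bd$score))
    stop("every detection must carry a score")
  classes <- sort(unique(bt$label))
  if (length(classes) == 0L) stop("ground truth contains no boxes")
  ap <- vapply(classes, function(cl) {
    ap11point(bd[bd$label == cl, , drop = FALSE],
              bt[bt$label == cl, , drop = FALSE],
              iou_threshold = iou_threshold)$ap
  }, numeric(1))
  counts <- do.call(rbind, lapply(classes, function(cl) {
    dcl <- bd[bd$label == cl & bd$score >= score_threshold, , drop = FALSE]
    tcl <- bt[bt$label == cl, , drop = FALSE]
    if (nrow(dcl)) {
      dcl <- dcl[order(-dcl$score), , drop = FALSE]
      tp <- sum(.greedyTP(dcl, tcl, iou_threshold))
    } else tp <- 0L
    data.frame(label = cl, n_truth = nrow(tcl), tp = tp,
               fp = nrow(dcl) - tp, fn = nrow(tcl) - tp,
               stringsAsFactors = FALSE)
  }))
  new("EvalReport",
      perClassAP = ap,
      map50 = mean(ap, na.rm = TRUE),
      counts = counts,
      iouThreshold = iou_threshold,
      scoreThreshold = score_threshold)
}

#' @describeIn EvalReport-class mean AP over ground-truth classes.
#' @param x An `EvalReport`.
#' @export
map50 <- function(x) {
  stopifnot(is(x, "EvalReport"))
  x@map50
}

#' @describeIn EvalReport-class named per-class AP vector.
#' @export
perClassAP <- function(x) {
  stopifnot(is(x, "EvalReport"))
  x@perClassAP
}

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (IoU >= %.2f, operating score >= %.2f)\n",
              object@iouThreshold, object@scoreThreshold))
  cat(sprintf("  mAP: %.4f over %d class(es)\n",
              object@map50, length(object@perClassAP)))
  for (cl in names(object@perClassAP))
    cat(sprintf("    %-20s AP %.4f\n", cl, object@perClassAP[cl]))
})

#' Serialize an EvalReport to a plain list / JSON file
#'
#' @param x An [EvalReport-class].
#' @param path optional JSON file to write.
#' @return The plain-list form (invisibly when writing).
#' @export
evalReportToList <- function(x, path = NULL) {
  stopifnot(is(x, "EvalReport"))
  out <- list(map50 = x@map50,
              per_class_ap = as.list(x@perClassAP),
              counts = x@counts,
              iou_threshold = x@iouThreshold,
              score_threshold = x@scoreThreshold)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    return(invisible(out))
  }
  out
}
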