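# Independent reference implementations used as oracles. Deliberately written
# as plain nested loops, separate from the package's vectorised code paths.

# one image, one category: c(left, top, right, bottom) rows
iou_ref <- function(a, b) {
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / ((a[3] - a[1]) * (a[4] - a[2]) +
           (b[3] - b[1]) * (b[4] - b[2]) - inter)
}

# exhaustive enumeration of all same-label (clean, noisy) pairs of one image;
# returns for each clean row index the matched noisy row index (or NA)
match_ref <- function(clean_df, noisy_df) {
  out <- rep(NA_integer_, nrow(clean_df))
  for (i in seq_len(nrow(clean_df))) {
    best <- 0; best_j <- NA_integer_
    for (j in seq_len(nrow(noisy_df))) {
      if (clean_df$label[i] != noisy_df$label[j]) next
      v <- iou_ref(as.numeric(clean_df[i, c("left", "top", "right", "bottom")]),
                   as.numeric(noisy_df[j, c("left", "top", "right", "bottom")]))
      if (v > best) { best <- v; best_j <- j }
    }
    out[i] <- best_j
  }
  out
}

# 11-point AP by sweeping every rank cutoff of the score-ordered list and
# recomputing the greedy assignment of each prefix from scratch
ap_ref <- function(det_df, truth_df, thr = 0.5) {
  if (nrow(truth_df) == 0L) return(if (nrow(det_df)) 0 else NA_real_)
  if (nrow(det_df) == 0L) return(0)
  det_df <- det_df[order(-det_df$score), , drop = FALSE]
  n <- nrow(det_df)
  prec <- rec <- numeric(n)
  for (k in seq_len(n)) {
    used <- rep(FALSE, nrow(truth_df))
    tp <- 0L
    for (i in seq_len(k)) {
      best <- -1; best_j <- 0L
      for (j in seq_len(nrow(truth_df))) {
        if (used[j] || truth_df$image_id[j] != det_df$image_id[i]) next
        v <- iou_ref(
          as.numeric(truth_df[j, c("left", "top", "right", "bottom")]),
          as.numeric(det_df[i, c("left", "top", "right", "bottom")]))
        if (v > best) { best <- v; best_j <- j }
      }
      if (best_j > 0L && best >= thr) { tp <- tp + 1L; used[best_j] <- TRUE }
    }
    prec[k] <- tp / k
    rec[k] <- tp / nrow(truth_df)
  }
  levels <- seq(0, 1, by = 0.1)
  mean(sapply(levels, function(r) {
    p <- prec[rec >= r]
    if (length(p)) max(p) else 0
  }))
}
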