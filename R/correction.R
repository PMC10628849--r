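#' Convex combination of a proposal box and a noisy box
#'
#' The corrected box is \eqn{\lambda B^* + (1 - \lambda) B} applied to each
#' of the four coordinates, where \eqn{B^*} is the corrector's proposal and
#' \eqn{B} the current (noisy) annotation. \eqn{\lambda = 1} returns the
#' proposal, \eqn{\lambda = 0} the noisy box.
#'
#' @param proposal,noisy single boxes: numeric `c(left, top, right, bottom)`
#'   or one-row data.frames with those columns (and, when both carry a
#'   `label`, matching labels).
#' @param lam merge weight \eqn{\lambda \in [0, 1]} given to the proposal.
#' @return numeric `c(left, top, right, bottom)` of the merged box.
#' @export
mergeBoxes <- function(proposal, noisy, lam) {
  stopifnot(length(lam) == 1L, lam >= 0, lam <= 1)
  if (is.data.frame(proposal) && is.data.frame(noisy) &&
      "label" %in% names(proposal) && "label" %in% names(noisy) &&
      !identical(proposal$label, noisy$label))
    stop(sprintf("label mismatch: '%s' vs '%s'",
                 proposal$label, noisy$label))
  p <- .asCoords(proposal); q <- .asCoords(noisy)
  out <- c(left = lam * p$left + (1 - lam) * q$left,
           top = lam * p$top + (1 - lam) * q$top,
           right = lam * p$right + (1 - lam) * q$right,
           bottom = lam * p$bottom + (1 - lam) * q$bottom)
  if (out["right"] <= out["left"] || out["bottom"] <= out["top"])
    stop("merged box is degenerate")
  out
}

#' Merge two aligned annotation sets box-by-box
#'
#' Index-aligned, set-wide version of [mergeBoxes()]: the k-th box of each
#' image in `proposals` is merged with the k-th box of the same image in
#' `noisy`. The sets must be structurally aligned (same image_ids, same
#' per-image box counts, same labels in order); a violation raises an error
#' naming the offending image.
#'
#' @param proposals,noisy aligned [AnnotationSet-class] objects.
#' @param lam merge weight \eqn{\lambda \in [0, 1]} given to the proposals.
#' @return An [AnnotationSet-class] with merged coordinates; labels, scores
#'   and structure come from `noisy`.
#' @export
mergeSets <- function(proposals, noisy, lam) {
  stopifnot(is(proposals, "AnnotationSet"), is(noisy, "AnnotationSet"),
            length(lam) == 1L, lam >= 0, lam <= 1)
  .checkAligned(proposals, noisy, what = "proposal and noisy sets")
  bp <- annotationBoxes(proposals)
  bn <- annotationBoxes(noisy)
  out <- bn
  for (col in .BOUNDARIES)
    out[[col]] <- lam * bp[[col]] + (1 - lam) * bn[[col]]
  AnnotationSet(out, imageInfo(noisy))
}

#' Oracle corrector for desk-scale correction-loop studies
#'
#' Builds a corrector function that stands in for a trained teacher
#' detector: for every box of the set it is given, it proposes the
#' corresponding hidden-truth box perturbed at noise level
#' \eqn{\rho \gamma_0} (fresh, independent draws on every call, emulating a
#' re-trained teacher). Fidelity \eqn{\rho = 0} reproduces the truth
#' exactly; \eqn{\rho = 1} proposes boxes as noisy as the initial set.
#'
#' @param truth the hidden reference [AnnotationSet-class], structurally
#'   aligned with the sets the corrector will be called on.
#' @param rho fidelity in \eqn{[0, 1]} (fraction of `gamma0` remaining in
#'   the proposals).
#' @param gamma0 the baseline noise level \eqn{\gamma_0} of the degraded set.
#' @param seed integer; call `k` of the corrector uses stream `seed + k - 1`.
#' @return A corrector: `function(current)` returning a proposal
#'   [AnnotationSet-class] aligned with `current`.
#' @seealso [runIterations()]
#' @export
makeOracleCorrector <- function(truth, rho, gamma0, seed = 1L) {
  stopifnot(is(truth, "AnnotationSet"), rho >= 0, rho <= 1, gamma0 >= 0)
  calls <- 0L
  function(current) {
    stopifnot(is(current, "AnnotationSet"))
    .checkAligned(truth, current, what = "truth and current sets")
    calls <<- calls + 1L
    synthesizeNoise(truth, gamma = rho * gamma0, seed = seed + calls - 1L,
                    clip = FALSE)
  }
}

#' Iterative teacher-student annotation correction
#'
#' Runs the correction loop: at each iteration the corrector (a teacher
#' model, or [makeOracleCorrector()] at desk scale) proposes one box per
#' current annotation, and the current set is replaced by the convex merge
#' of proposals and current boxes ([mergeSets()]). Each iteration re-merges
#' against the previously corrected set, so the label set is refined
#' cumulatively. With an imperfect but informative corrector the noise
#' level \eqn{\gamma} against the hidden truth decreases towards the fixed
#' point of the variance recursion
#' \eqn{v_{k+1} = \lambda^2 (\rho\gamma_0)^2 + (1-\lambda)^2 v_k} and then
#' plateaus, which is why a small iteration count (default 3) suffices.
#'
#' @param initial the starting (degraded) [AnnotationSet-class].
#' @param corrector a function taking the current set and returning an
#'   aligned proposal set.
#' @param n_iter number of iterations \eqn{N \ge 0} (default 3).
#' @param lam merge weight \eqn{\lambda} given to proposals.
#' @param reference optional hidden truth; when given, \eqn{\gamma} of the
#'   current set against it is recorded at every step via [noiseReport()].
#' @return list with `set` (the corrected [AnnotationSet-class]) and
#'   `trace` (data.frame of `n_iter + 1` rows: `iteration` 0..N, `gamma`
#'   vs reference or `NA`, and a `checksum` fingerprint of the label set).
#' @examples
#' truth <- generateAnnotations(30, seed = 1)
#' noisy <- synthesizeNoise(truth, gamma = 0.15, seed = 2)
#' corr <- makeOracleCorrector(truth, rho = 0.5, gamma0 = 0.15, seed = 3)
#' res <- runIterations(noisy, corr, n_iter = 3, lam = 0.5, reference = truth)
#' res$trace
#' @export
runIterations <- function(initial, corrector, n_iter = 3L, lam = 0.5,
                          reference = NULL) {
  stopifnot(is(initial, "AnnotationSet"), is.function(corrector),
            n_iter >= 0)
  gammaVs <- function(s) {
    if (is.null(reference)) return(NA_real_)
    gammaOverall(noiseReport(reference, s))
  }
  current <- initial
  trace <- data.frame(iteration = 0L, gamma = gammaVs(current),
                      checksum = .setChecksum(current),
                      stringsAsFactors = FALSE)
  for (k in seq_len(n_iter)) {
    proposals <- corrector(current)
    current <- mergeSets(proposals, current, lam)
    trace <- rbind(trace, data.frame(
      iteration = k, gamma = gammaVs(current),
      checksum = .setChecksum(current), stringsAsFactors = FALSE))
  }
  rownames(trace) <- NULL
  list(set = current, trace = trace)
}

#' Closed-form gamma trajectory of the oracle correction loop
#'
#' Companion to [runIterations()] with [makeOracleCorrector()]: with
#' independent proposal noise \eqn{\rho\gamma_0} and merge weight
#' \eqn{\lambda}, the relative-error variance follows
#' \eqn{v_{k+1} = \lambda^2(\rho\gamma_0)^2 + (1-\lambda)^2 v_k} from
#' \eqn{v_0 = \gamma_0^2}, with fixed point
#' \eqn{\gamma_\infty = \lambda\rho\gamma_0 / \sqrt{1 - (1-\lambda)^2}}
#' (for \eqn{\lambda > 0}).
#'
#' @param gamma0 initial noise level.
#' @param rho corrector fidelity.
#' @param lam merge weight.
#' @param n_iter number of iterations.
#' @return data.frame (`iteration` 0..`n_iter`, `gamma`).
#' @export
gammaRecursion <- function(gamma0, rho, lam, n_iter) {
  v <- gamma0^2
  out <- numeric(n_iter + 1L)
  out[1] <- gamma0
  for (k in seq_len(n_iter)) {
    v <- lam^2 * (rho * gamma0)^2 + (1 - lam)^2 * v
    out[k + 1L] <- sqrt(v)
  }
  data.frame(iteration = 0:n_iter, gamma = out)
}
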