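# run code under a temporary, seeded RNG state, restoring the caller's state
.withSeed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthesize size-proportional Gaussian localization noise
#'
#' Perturbs every box of a clean annotation set with the generative law the
#' noise diagnostics assume: each of the four boundaries independently
#' receives an absolute error \eqn{\Delta \sim N(0, (\gamma S)^2)}, where
#' \eqn{S} is the clean box width for the left/right boundaries and the
#' clean height for top/bottom. The noisy boundary is the clean boundary
#' minus \eqn{\Delta}, so that clean \eqn{-} noisy \eqn{= \Delta}, matching
#' the sign convention of [boundaryErrors()]. Labels, scores, image ids and
#' per-image box counts are untouched, so the output aligns with the input.
#'
#' If a draw collapses a box below `minSide` pixels on either side (after
#' clipping when `clip = TRUE`), that box is redrawn up to `maxResample`
#' times; as a last resort the clean box itself (expanded to `minSide` and
#' clamped if needed) is used, so the result is always valid.
#'
#' Boxes are traversed in the set's canonical order (sorted `image_id`,
#' stable within an image) with a single seeded RNG stream, so identical
#' inputs give byte-identical outputs.
#'
#' @param x a clean [AnnotationSet-class].
#' @param gamma noise level \eqn{\gamma \ge 0} (RMS relative error).
#' @param seed integer seed for the synthesis stream.
#' @param maxResample redraw attempts per degenerate box.
#' @param minSide smallest admissible box side, pixels.
#' @param clip clamp perturbed boxes to their image bounds. The default
#'   suits label sets destined for files; set `FALSE` when measuring the
#'   unbounded generative law itself (border clamping slightly shrinks the
#'   error moments of boxes near image edges).
#' @return An [AnnotationSet-class] with the same structure as `x`.
#' @examples
#' truth <- generateAnnotations(10, seed = 1)
#' noisy <- synthesizeNoise(truth, gamma = 0.15, seed = 7)
#' @export
synthesizeNoise <- function(x, gamma, seed = 1L, maxResample = 25L,
                            minSide = 1.0, clip = TRUE) {
  stopifnot(is(x, "AnnotationSet"), gamma >= 0, maxResample >= 1)
  b <- annotationBoxes(x)
  if (nrow(b) == 0L) return(x)
  d <- .boxImageDims(b, imageInfo(x))
  .withSeed(seed, {
    res <- .perturbFrame(b, d$width, d$height, gamma = gamma,
                         maxResample = maxResample, minSide = minSide,
                         clip = clip)
    AnnotationSet(res, imageInfo(x))
  })
}

# vectorised perturbation with resample-then-fallback; consumes the current
# RNG stream in box order (4 draws per box per round)
.perturbFrame <- function(b, W, H, gamma, maxResample, minSide, clip) {
  n <- nrow(b)
  w <- b$right - b$left
  h <- b$bottom - b$top
  out <- b
  pending <- seq_len(n)
  for (round in seq_len(maxResample)) {
    if (length(pending) == 0L) break
    m <- length(pending)
    # 4 draws per pending box, boundary-major within a box
    dl <- stats::rnorm(m, 0, gamma * w[pending])
    dt <- stats::rnorm(m, 0, gamma * h[pending])
    dr <- stats::rnorm(m, 0, gamma * w[pending])
    db <- stats::rnorm(m, 0, gamma * h[pending])
    nl <- b$left[pending] - dl
    nt <- b$top[pending] - dt
    nr <- b$right[pending] - dr
    nb <- b$bottom[pending] - db
    if (clip) {
      nl <- pmin(pmax(nl, 0), W[pending])
      nr <- pmin(pmax(nr, 0), W[pending])
      nt <- pmin(pmax(nt, 0), H[pending])
      nb <- pmin(pmax(nb, 0), H[pending])
    }
    ok <- (nr - nl >= minSide) & (nb - nt >= minSide)
    keep <- pending[ok]
    out$left[keep] <- nl[ok]
    out$top[keep] <- nt[ok]
    out$right[keep] <- nr[ok]
    out$bottom[keep] <- nb[ok]
    pending <- pending[!ok]
  }
  if (length(pending)) {
    # fallback: the clean box, expanded to minSide around its centre
    for (i in pending) {
      box <- .expandToMinSide(b[i, ], W[i], H[i], minSide, clip)
      out[i, .BOUNDARIES] <- box
    }
  }
  out
}

.expandToMinSide <- function(row, W, H, minSide, clip) {
  l <- row$left; t <- row$top; r <- row$right; bm <- row$bottom
  if (r - l < minSide) {
    cx <- (l + r) / 2
    l <- cx - minSide / 2; r <- cx + minSide / 2
  }
  if (bm - t < minSide) {
    cy <- (t + bm) / 2
    t <- cy - minSide / 2; bm <- cy + minSide / 2
  }
  if (clip) {
    if (l < 0) { r <- r - l; l <- 0 }
    if (t < 0) { bm <- bm - t; t <- 0 }
    if (r > W) { l <- l - (r - W); r <- W }
    if (bm > H) { t <- t - (bm - H); bm <- H }
  }
  data.frame(left = l, top = t, right = r, bottom = bm)
}
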