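test_that("identical sets match every box at IoU 1", {
  set <- generateAnnotations(8, seed = 1)
  m <- matchBoxes(set, set)
  expect_identical(nrow(m$pairs), nBoxes(set))
  expect_identical(m$n_unmatched_clean, 0L)
  expect_true(all(m$pairs$iou == 1))
})

test_that("the maximum-IoU same-label candidate is selected", {
  clean <- toy_set(box_row(0, 0, 100, 100))
  # IoU with clean: 60/(100+60-60) wide overlap vs a small one
  noisy <- toy_set(box_row(0, 0, 60, 100),   # IoU = 0.6
                   box_row(0, 0, 30, 100))   # IoU = 0.3
  m <- matchBoxes(clean, noisy)
  expect_identical(nrow(m$pairs), 1L)
  expect_equal(m$pairs$noisy_right, 60)
  expect_equal(m$pairs$iou, 0.6)
})

test_that("overlap under a different label yields no match", {
  clean <- toy_set(box_row(0, 0, 100, 100, label = "gray_mold"))
  noisy <- toy_set(box_row(0, 0, 100, 100, label = "powdery_mildew"))
  m <- matchBoxes(clean, noisy)
  expect_identical(nrow(m$pairs), 0L)
  expect_identical(m$n_unmatched_clean, 1L)
})

test_that("dimension mismatches error and one-sided images are skipped", {
  clean <- AnnotationSet(box_row(0, 0, 10, 10), one_image(size = 640))
  noisy <- AnnotationSet(box_row(0, 0, 10, 10), one_image(size = 512))
  expect_error(matchBoxes(clean, noisy), "dimension mismatch")
  a <- AnnotationSet(box_row(0, 0, 10, 10, image_id = "x"),
                     rbind(one_image("x"), one_image("only_a")))
  b <- AnnotationSet(box_row(0, 0, 10, 10, image_id = "x"), one_image("x"))
  m <- matchBoxes(a, b)
  expect_identical(m$images_skipped, "only_a")
})

test_that("matching agrees with exhaustive pair enumeration", {
  set.seed(99)
  for (rep in 1:20) {
    n_clean <- sample(1:10, 1)
    n_noisy <- sample(1:10, 1)
    mk <- function(n) {
      l <- runif(n, 0, 600); t <- runif(n, 0, 600)
      data.frame(image_id = "img",
                 label = sample(c("a", "b"), n, replace = TRUE),
                 score = NA_real_, left = l, top = t,
                 right = l + runif(n, 5, 40), bottom = t + runif(n, 5, 40),
                 stringsAsFactors = FALSE)
    }
    cdf <- mk(n_clean); ndf <- mk(n_noisy)
    m <- matchBoxes(AnnotationSet(cdf, one_image()),
                    AnnotationSet(ndf, one_image()))
    ref <- match_ref(cdf, ndf)
    expect_identical(nrow(m$pairs), sum(!is.na(ref)))
    expect_identical(m$n_unmatched_clean, sum(is.na(ref)))
    if (nrow(m$pairs)) {
      got <- m$pairs[order(m$pairs$clean_left), ]
      want <- cdf[!is.na(ref), ]
      want_n <- ndf[ref[!is.na(ref)], ]
      o <- order(want$left)
      expect_equal(got$clean_left, want$left[o])
      expect_equal(got$noisy_left, want_n$left[o])
      expect_equal(got$noisy_bottom, want_n$bottom[o])
    }
  }
})

test_that("boundary errors follow the clean-minus-noisy sign convention", {
  clean <- toy_set(box_row(10, 10, 110, 210))
  noisy <- toy_set(box_row(5, 10, 120, 210))
  err <- boundaryErrors(matchBoxes(clean, noisy)$pairs)
  expect_identical(nrow(err), 4L)
  get <- function(bd, col) err[err$boundary == bd, col]
  expect_equal(get("left", "delta"), 5)
  expect_equal(get("right", "delta"), -10)
  expect_equal(get("top", "delta"), 0)
  expect_equal(get("bottom", "delta"), 0)
  expect_equal(get("left", "scale"), 100)   # clean width
  expect_equal(get("top", "scale"), 200)    # clean height
  expect_equal(get("left", "relative"), 0.05)
  expect_equal(get("right", "relative"), -0.10)
  # identity pair: all zeros
  err0 <- boundaryErrors(matchBoxes(clean, clean)$pairs)
  expect_true(all(err0$delta == 0) && all(err0$relative == 0))
})

test_that("size classes split at 0.1 and 0.3 of the image dimension", {
  expect_identical(sizeClass(32, 640), "small")    # 0.05
  expect_identical(sizeClass(64, 640), "small")    # boundary, inclusive
  expect_identical(sizeClass(128, 640), "middle")  # 0.2
  expect_identical(sizeClass(192, 640), "middle")  # boundary, inclusive
  expect_identical(sizeClass(320, 640), "large")   # 0.5
  expect_error(sizeClass(700, 640), "exceeds")
  expect_error(sizeClass(0, 640), "positive")
})

test_that("gamma and sigma reproduce hand-computed values", {
  expect_equal(gammaError(c(0, 0, 0), c(10, 20, 30)), 0)
  expect_equal(gammaError(15, 100), 0.15)
  expect_equal(gammaError(c(3, 4), c(10, 10)), sqrt(0.125))
  expect_equal(sigmaError(c(0, 0)), 0)
  expect_equal(sigmaError(c(3, 4)), sqrt(12.5))
  expect_equal(sigmaError(-7), 7)
  expect_error(gammaError(numeric(), numeric()), "no boundary errors")
  expect_error(sigmaError(numeric()), "no boundary errors")
})

test_that("binned sigma groups by rescaled size and drops thin bins", {
  err <- data.frame(image_id = "img", boundary = "left",
                    delta = rep(c(10, -10), 10), scale = 100,
                    relative = rep(c(0.1, -0.1), 10), image_dim = 640,
                    size_class = "middle", stringsAsFactors = FALSE)
  bs <- binnedSigma(err)
  expect_identical(nrow(bs), 1L)
  expect_equal(bs$s_bar, 100)
  expect_equal(bs$sigma_local, 10)
  # two populated bins come out ordered by size
  err2 <- err
  err2$scale <- rep(c(40, 200), each = 10)
  bs2 <- binnedSigma(err2)
  expect_identical(nrow(bs2), 2L)
  expect_true(bs2$s_bar[1] < bs2$s_bar[2])
  # a bin with fewer than min_count errors is dropped
  err3 <- rbind(err, transform(err[1:3, ], scale = 500))
  expect_identical(nrow(binnedSigma(err3)), 1L)
  # rescaling multiplies both size and error by rescale_to / image_dim
  err4 <- err
  err4$image_dim <- 1280
  bs4 <- binnedSigma(err4)
  expect_equal(bs4$s_bar, 50)
  expect_equal(bs4$sigma_local, 5)
})

test_that("through-origin slope fit matches the closed form", {
  pts <- data.frame(s_bar = c(50, 150, 300),
                    sigma_local = 0.15 * c(50, 150, 300))
  expect_equal(fitSigmaSlope(pts), 0.15)
  expect_equal(fitSigmaSlope(data.frame(s_bar = c(10, 20),
                                        sigma_local = c(0, 0))), 0)
  pts3 <- data.frame(s_bar = c(100, 200, 400), sigma_local = c(10, 20, 44))
  expect_equal(fitSigmaSlope(pts3), 22600 / 210000)
  expect_error(fitSigmaSlope(pts3[1, , drop = FALSE]), "at least 2")
})

test_that("boundary correlations match cor() on hand-listed series", {
  pairs <- matchBoxes(
    toy_set(box_row(0, 0, 100, 100), box_row(200, 200, 300, 300),
            box_row(400, 400, 500, 500)),
    toy_set(box_row(2, 1, 103, 99), box_row(195, 204, 301, 298),
            box_row(403, 399, 498, 503)))$pairs
  expect_identical(nrow(pairs), 3L)
  bc <- boundaryCorrelation(pairs)
  rel <- cbind((pairs$clean_left - pairs$noisy_left) / 100,
               (pairs$clean_top - pairs$noisy_top) / 100,
               (pairs$clean_right - pairs$noisy_right) / 100,
               (pairs$clean_bottom - pairs$noisy_bottom) / 100)
  expect_equal(unname(bc$r), cor(rel))
  expect_true(all(bc$defined))
  expect_equal(unname(diag(bc$r)), rep(1, 4))
})

test_that("duplicated series correlate at 1 and constant series are flagged", {
  # noisy differs from clean by the same shift on left and top
  pairs <- matchBoxes(
    toy_set(box_row(0, 0, 100, 100), box_row(200, 200, 300, 300),
            box_row(400, 400, 500, 500)),
    toy_set(box_row(5, 5, 100, 100), box_row(190, 190, 300, 300),
            box_row(402, 402, 500, 500)))$pairs
  bc <- boundaryCorrelation(pairs)
  expect_equal(bc$r["left", "top"], 1)
  # right and bottom series are constant zero: undefined, flagged not NaN
  expect_false(bc$defined["left", "right"])
  expect_true(is.na(bc$r["left", "right"]))
  expect_true(bc$defined["left", "left"])
})

test_that("noiseReport aggregates matching, errors and exclusions", {
  truth <- generateAnnotations(15, seed = 5)
  rep0 <- noiseReport(truth, truth)
  expect_equal(gammaOverall(rep0), 0)
  expect_false(any(rep0@correlationDefined[upper.tri(diag(4))]))
  # a clean box with no same-label counterpart is excluded, not scored
  clean <- toy_set(box_row(0, 0, 100, 100, label = "gray_mold"),
                   box_row(300, 300, 400, 400, label = "powdery_mildew"))
  noisy <- toy_set(box_row(2, 1, 98, 99, label = "gray_mold"),
                   box_row(300, 300, 400, 400, label = "spider_mite"))
  rep1 <- noiseReport(clean, noisy, min_count = 1)
  expect_identical(rep1@nPairs, 1L)
  expect_identical(rep1@nUnmatchedClean, 1L)
  expect_identical(nrow(reportErrors(rep1)), 4L)
  expect_error(noiseReport(truth, generateAnnotations(0)), "share no image")
})
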