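test_that("box merge endpoints and midpoint follow the convex combination", {
  p <- c(0, 0, 10, 10)
  q <- c(2, 2, 12, 12)
  expect_equal(unname(mergeBoxes(p, q, lam = 1)), p)
  expect_equal(unname(mergeBoxes(p, q, lam = 0)), q)
  expect_equal(unname(mergeBoxes(p, q, lam = 0.5)), c(1, 1, 11, 11))
  expect_error(mergeBoxes(p, q, lam = 1.5))
  expect_error(mergeBoxes(box_row(0, 0, 10, 10, label = "a"),
                          box_row(0, 0, 10, 10, label = "b"), lam = 0.5),
               "label mismatch")
  # a degenerate convex combination is rejected
  expect_error(mergeBoxes(c(0, 0, 1, 1), c(1, 1, 0.5, 0.5), lam = 0),
               "degenerate")
})

test_that("set-wide merge is elementwise and a fixed point on equal inputs", {
  truth <- generateAnnotations(5, seed = 21)
  noisy <- synthesizeNoise(truth, gamma = 0.1, seed = 22)
  for (lam in c(0, 0.3, 1))
    expect_equal(annotationBoxes(mergeSets(noisy, noisy, lam)),
                 annotationBoxes(noisy))
  half <- mergeSets(truth, noisy, lam = 0.5)
  expect_equal(annotationBoxes(half)$left,
               (annotationBoxes(truth)$left + annotationBoxes(noisy)$left) / 2)
  expect_equal(annotationBoxes(half)$bottom,
               (annotationBoxes(truth)$bottom +
                  annotationBoxes(noisy)$bottom) / 2)
})

test_that("alignment violations name the offending image", {
  a <- AnnotationSet(rbind(box_row(0, 0, 10, 10, image_id = "x"),
                           box_row(0, 0, 10, 10, image_id = "y")),
                     rbind(one_image("x"), one_image("y")))
  b <- AnnotationSet(rbind(box_row(0, 0, 10, 10, image_id = "x"),
                           box_row(0, 0, 10, 10, image_id = "y"),
                           box_row(20, 20, 30, 30, image_id = "y")),
                     rbind(one_image("x"), one_image("y")))
  expect_error(mergeSets(a, b, lam = 0.5), "y")
  lab <- AnnotationSet(rbind(box_row(0, 0, 10, 10, image_id = "x",
                                     label = "other"),
                             box_row(0, 0, 10, 10, image_id = "y")),
                       rbind(one_image("x"), one_image("y")))
  expect_error(mergeSets(a, lab, lam = 0.5), "label mismatch")
})

test_that("a perfect oracle reproduces the hidden truth", {
  truth <- generateAnnotations(20, seed = 23)
  noisy <- synthesizeNoise(truth, gamma = 0.15, seed = 24, clip = FALSE)
  corr <- makeOracleCorrector(truth, rho = 0, gamma0 = 0.15, seed = 25)
  expect_equal(annotationBoxes(corr(noisy)), annotationBoxes(truth))
  # rho = 0 with lam = 1 corrects exactly in one iteration
  res <- runIterations(noisy, corr, n_iter = 1, lam = 1, reference = truth)
  expect_equal(res$trace$gamma[2], 0)
  expect_equal(annotationBoxes(res$set), annotationBoxes(truth))
})

test_that("oracle proposals carry the configured noise and are seeded", {
  truth <- generateAnnotations(1200, size_range = c(32, 480), seed = 26)
  noisy <- synthesizeNoise(truth, gamma = 0.15, seed = 27, clip = FALSE)
  corr1 <- makeOracleCorrector(truth, rho = 1, gamma0 = 0.15, seed = 28)
  corr2 <- makeOracleCorrector(truth, rho = 1, gamma0 = 0.15, seed = 28)
  p1 <- corr1(noisy)
  expect_identical(annotationBoxes(p1), annotationBoxes(corr2(noisy)))
  # consecutive calls draw fresh noise
  expect_false(identical(annotationBoxes(p1), annotationBoxes(corr1(noisy))))
  g <- gammaOverall(noiseReport(truth, p1))
  expect_equal(g, 0.15, tolerance = 3 / sqrt(2 * 4 * nBoxes(truth)))
})

test_that("zero iterations return the input with a length-1 trace", {
  truth <- generateAnnotations(5, seed = 29)
  noisy <- synthesizeNoise(truth, gamma = 0.1, seed = 30)
  corr <- makeOracleCorrector(truth, rho = 0.5, gamma0 = 0.1, seed = 31)
  res <- runIterations(noisy, corr, n_iter = 0, reference = truth)
  expect_identical(nrow(res$trace), 1L)
  expect_equal(annotationBoxes(res$set), annotationBoxes(noisy))
})

test_that("the gamma trace follows the closed-form variance recursion", {
  truth <- generateAnnotations(1700, size_range = c(32, 480), seed = 32)
  gamma0 <- 0.15; rho <- 0.5; lam <- 0.5; iters <- 6
  noisy <- synthesizeNoise(truth, gamma = gamma0, seed = 33, clip = FALSE)
  corr <- makeOracleCorrector(truth, rho = rho, gamma0 = gamma0, seed = 34)
  res <- runIterations(noisy, corr, n_iter = iters, lam = lam,
                       reference = truth)
  expected <- gammaRecursion(gamma0, rho, lam, iters)
  n_err <- 4 * nBoxes(truth)
  # each gamma_k within ~2 Monte-Carlo standard errors of the recursion
  for (k in seq_len(iters + 1))
    expect_equal(res$trace$gamma[k], expected$gamma[k],
                 tolerance = 3 / sqrt(2 * n_err))
  # fixed point: gamma_inf = lam * rho * gamma0 / sqrt(1 - (1 - lam)^2)
  fix <- lam * rho * gamma0 / sqrt(1 - (1 - lam)^2)
  expect_equal(res$trace$gamma[iters + 1], fix, tolerance = 0.05)
  # plateau: converged iterations change gamma by < 5% relative
  expect_lt(abs(res$trace$gamma[iters + 1] - res$trace$gamma[iters]) /
              res$trace$gamma[iters], 0.05)
})

test_that("gamma vs truth is non-increasing for an informative corrector", {
  truth <- generateAnnotations(1200, size_range = c(32, 480), seed = 35)
  noisy <- synthesizeNoise(truth, gamma = 0.15, seed = 36, clip = FALSE)
  corr <- makeOracleCorrector(truth, rho = 0.5, gamma0 = 0.15, seed = 37)
  res <- runIterations(noisy, corr, n_iter = 4, lam = 0.5, reference = truth)
  g <- res$trace$gamma
  se <- 2 * g[1] / sqrt(2 * 4 * nBoxes(truth))
  expect_true(all(diff(g) <= se))
})

test_that("the corrector contract is enforced at call time", {
  truth <- generateAnnotations(4, seed = 38)
  other <- generateAnnotations(5, seed = 39)
  corr <- makeOracleCorrector(truth, rho = 0.5, gamma0 = 0.15, seed = 40)
  expect_error(corr(other), "not aligned")
})
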