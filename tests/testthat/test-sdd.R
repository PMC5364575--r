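test_that("rescaling maps images onto [0, 255] with round-half-up", {
  expect_equal(as.vector(rescale_to_255(matrix(c(0, 510), 1))), c(0, 255))
  expect_equal(as.vector(rescale_to_255(matrix(c(10, 20, 40), 1))),
               c(64, 128, 255))
  img <- matrix(c(0, 100, 255), 1)
  expect_equal(rescale_to_255(img), img)
  expect_error(rescale_to_255(matrix(0, 3, 3)), "all-zero")
})

test_that("the normalized histogram has a unit modal bin", {
  img <- matrix(c(rep(50, 60), rep(200, 40)), 10)
  p <- normalized_histogram(img)
  expect_equal(p[50 + 1], 1)
  expect_equal(p[200 + 1], 40 / 60)
  expect_equal(sum(p > 0), 2)

  expect_equal(normalized_histogram(matrix(7, 4, 4))[7 + 1], 1)
  # all gray levels equally frequent: every bin is the max
  u <- matrix(rep(0:255, 4), 32)
  expect_equal(normalized_histogram(u), rep(1, 256))

  expect_error(normalized_histogram(matrix(0.5, 2, 2)), "integer")
})

test_that("the DFT low-pass filter keeps the stated bands", {
  set.seed(3)
  sig <- abs(rnorm(256)) + 1          # non-negative, magnitude-safe
  expect_equal(dft_lowpass(sig, 128), sig, tolerance = 1e-9)
  expect_equal(dft_lowpass(rep(3, 256), 5), rep(3, 256), tolerance = 1e-12)

  x <- 0:255
  cosine <- cos(2 * pi * 3 * x / 256)
  expect_lt(max(dft_lowpass(cosine, 2)), 1e-10)     # bin 3 removed
  expect_equal(dft_lowpass(cosine, 3), abs(cosine), tolerance = 1e-10)

  # the k = 0 coefficient is untouched, so the mean is conserved for
  # non-negative signals
  expect_equal(mean(dft_lowpass(sig, 10)), mean(sig), tolerance = 1e-6)
  expect_error(dft_lowpass(sig, 0), "bandwidth")
  expect_error(dft_lowpass(sig[1:100], 5), "length 256")
})

test_that("slope difference of featureless and triangular histograms", {
  # straight line: both side slopes equal everywhere
  line <- seq(0.1, 1, length.out = 256)
  sdd <- slope_difference(line, 15)
  expect_lt(max(abs(sdd$s)), 1e-10)
  # any detected extrema are pure floating-point noise
  expect_true(all(abs(sdd$peaks$magnitude) < 1e-10))
  expect_true(all(abs(sdd$valleys$magnitude) < 1e-10))

  # symmetric triangle: apex is a density mode, i.e. an SDD peak; the base
  # corners, where the slope turns on/off, are valleys
  tri <- pmax(0, 1 - abs(0:255 - 128) / 60)
  sdd <- slope_difference(tri, 11)
  top <- sdd$peaks[which.max(sdd$peaks$magnitude), ]
  expect_lte(abs(top$position - 128), 1)
  expect_gt(top$magnitude, 0)
  vl <- sdd$valleys[order(sdd$valleys$magnitude), ][1:2, ]
  expect_true(all(abs(vl$position - 128) >= 56 &
                  abs(vl$position - 128) <= 64))
})

test_that("the dominant SDD peak locates a Gaussian cluster center", {
  for (center in c(90, 140, 180)) {
    hist <- dnorm(0:255, center, 12); hist <- hist / max(hist)
    sdd <- slope_difference(dft_lowpass(hist, 10), 15)
    top <- sdd$peaks[which.max(sdd$peaks$magnitude), ]
    expect_lte(abs(top$position - center), 2)
  }
})

test_that("real-peak selection keeps the largest-magnitude peaks", {
  tc <- make_three_class()
  sm <- dft_lowpass(normalized_histogram(tc$image), 10)
  sdd <- slope_difference(sm, 15)
  peaks <- select_real_peaks(sdd, 3)
  expect_equal(length(peaks), 3)
  expect_true(all(abs(peaks - c(50, 120, 220)) <= 2))
  expect_error(select_real_peaks(sdd, 50), "recalibrate")

  # unimodal histogram, K_c = 1
  uni <- dnorm(0:255, 100, 15); uni <- uni / max(uni)
  sdd1 <- slope_difference(dft_lowpass(uni, 10), 15)
  expect_lte(abs(select_real_peaks(sdd1, 1) - 100), 2)
})

test_that("threshold selection brackets the requested classes", {
  tc <- make_three_class()
  th1 <- sdd_threshold(tc$image, class_count = 3, case_id = 1,
                       rescale = FALSE)
  expect_gt(th1$threshold, 50); expect_lt(th1$threshold, 120)
  th2 <- sdd_threshold(tc$image, class_count = 3, case_id = 2,
                       rescale = FALSE)
  expect_gt(th2$threshold, 120); expect_lt(th2$threshold, 220)
  # threshold always strictly between its bounding peaks and inside [0, 255]
  for (th in list(th1, th2)) {
    expect_gt(th$threshold, th$bounds[1])
    expect_lt(th$threshold, th$bounds[2])
  }
})

test_that("two-Gaussian thresholds track the misclassification optimum", {
  set.seed(11)
  mix <- random_mixture()
  th <- sdd_threshold(mix$image, rescale = FALSE)
  oracle <- oracle_mixture_threshold(mix$w1, mix$mu1, mix$s1, mix$mu2, mix$s2)
  expect_lte(abs(th$threshold - oracle), 3)
})

test_that("extremum classification separates harmonics from real features", {
  tc <- make_three_class()
  sdd <- slope_difference(dft_lowpass(normalized_histogram(tc$image), 10), 15)
  cls <- classify_extrema(sdd)
  expect_equal(nrow(cls$peaks), 3)
  expect_equal(nrow(cls$valleys), 6)
  # a permissive fraction admits pseudo extrema
  expect_gt(nrow(classify_extrema(sdd, 0.02)$valleys), 6)
})
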