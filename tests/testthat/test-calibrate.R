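test_that("F-measure equals the Dice coefficient and handles edge cases", {
  m <- matrix(FALSE, 10, 10)
  a <- m; a[2:5, 2:5] <- TRUE
  expect_equal(f_measure(a, a), 1)
  b <- m; b[7:9, 7:9] <- TRUE
  expect_equal(f_measure(a, b), 0)

  # automatic mask strictly inside the manual one: F = 2*50/(100+50)
  man <- m; man[1:10, 1:10] <- TRUE
  auto <- m; auto[1:5, 1:10] <- TRUE
  expect_equal(f_measure(auto, man), 2 * 50 / 150)

  set.seed(4)
  for (i in 1:20) {
    x <- matrix(runif(100) < 0.5, 10)
    y <- matrix(runif(100) < 0.5, 10)
    if (!any(y)) next
    dice <- 2 * sum(x & y) / (sum(x) + sum(y))
    expect_equal(f_measure(x, y), dice, tolerance = 1e-12)
  }
  expect_error(f_measure(a, m), "empty")
  expect_error(f_measure(a, matrix(TRUE, 3, 3)), "shape")
})

test_that("grid calibration recovers parameters that reproduce the truth", {
  img <- matrix(40, 80, 80)
  img[20:40, 20:40] <- 200; img[55:70, 50:70] <- 200
  truth <- img > 120
  noisy <- add_gaussian_noise(img, 8, seed = 5)
  cal <- calibrate_grid(list(noisy), list(truth),
                        n_range = 5:25, w_range = 4:16)
  th <- sdd_threshold(noisy, fit_points = cal$fit_points,
                      bandwidth = cal$bandwidth)
  expect_gte(f_measure(binarize(rescale_to_255(noisy), th$threshold), truth),
             0.99)
  expect_true(cal$fit_points %in% 5:25 && cal$bandwidth %in% 4:16)
})

test_that("grid calibration breaks ties toward the smallest parameters", {
  # only two gray levels: every (N, W) yields the same mask, so the
  # tie-break must return the smallest W, then the smallest N
  img <- matrix(40, 64, 64); img[20:45, 20:45] <- 200
  cal <- calibrate_grid(list(img), list(img > 120),
                        n_range = 3:6, w_range = 2:5)
  expect_equal(cal$fit_points, 3)
  expect_equal(cal$bandwidth, 2)
  expect_error(calibrate_grid(list(), list()), "nonempty")
})

test_that("rational calibration finds the N with the expected peak count", {
  tc <- make_three_class()
  cal <- calibrate_rational(tc$image, class_count = 3, rescale = FALSE)
  expect_equal(cal$fit_points, 15)     # defaults already show 3 peaks

  # two close bumps merge into one as N grows: start at 4 peaks, reach 3
  set.seed(6)
  v <- c(rnorm(16000, 60, 7), rnorm(6000, 125, 4), rnorm(6000, 145, 4),
         rnorm(9000, 215, 7))
  img <- matrix(pmin(pmax(round(v), 0), 255), 100)
  sm <- dft_lowpass(normalized_histogram(img), 10)
  n15 <- nrow(classify_extrema(slope_difference(sm, 15))$peaks)
  expect_gt(n15, 3)
  cal <- calibrate_rational(img, class_count = 3, rescale = FALSE)
  expect_gt(cal$fit_points, 15)
  nstar <- nrow(classify_extrema(slope_difference(sm, cal$fit_points))$peaks)
  expect_equal(nstar, 3)

  # unreachable class count
  expect_error(calibrate_rational(tc$image, class_count = 9, rescale = FALSE),
               "dominant peaks")
})

test_that("run_calibration wires results into the configuration", {
  tc <- make_three_class()
  cfg <- run_calibration(tc$image, mode = "rational",
                         config = pipeline_config(class_count = 3),
                         rescale = FALSE)
  expect_equal(cfg$n_intensity, 15)
  expect_error(run_calibration(tc$image, mode = "f_measure"), "ground truth")
})
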