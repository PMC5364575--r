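#' F-measure between an automatic and a manual segmentation
#'
#' `F = 2 P R / (P + R)` with `P = |A ∩ M| / |M|` and `R = |A ∩ M| / |A|`
#' (`A` automatic, `M` manual).  Algebraically this equals the Dice
#' coefficient `2 |A ∩ M| / (|A| + |M|)`; it is 0 when the masks are
#' disjoint and 1 when they are identical.
#'
#' @param auto_mask,manual_mask logical matrices of the same shape;
#'   `manual_mask` must be nonempty.
#' @return a number in `[0, 1]`.
#' @export
f_measure <- function(auto_mask, manual_mask) {
  assert_mask(auto_mask); assert_mask(manual_mask)
  if (!identical(dim(auto_mask), dim(manual_mask)))
    stop2("masks must have the same shape")
  if (!any(manual_mask)) stop2("manual mask is empty; F-measure undefined")
  inter <- sum(auto_mask & manual_mask)
  if (inter == 0) return(0)
  p <- inter / sum(manual_mask)
  r <- inter / sum(auto_mask)
  2 * p * r / (p + r)
}

#' Calibrate (N, W) by F-measure grid search
#'
#' Scans the line-fit count `N` and the DFT bandwidth `W` over their full
#' ranges; for every pair, each image is thresholded by the slope difference
#' distribution method, binarized, and scored with [f_measure()] against its
#' ground-truth mask; the pair maximizing the mean score wins.  A pair for
#' which threshold selection fails scores 0 for that image.  Ties are broken
#' toward the smallest `W`, then the smallest `N`.
#'
#' @param images list of numeric matrices.
#' @param truths list of logical matrices, same length and shapes.
#' @param class_count,case_id,polarity forwarded to [sdd_threshold()] /
#'   [binarize()].
#' @param n_range,w_range integer ranges scanned; defaults `3:60` and `2:50`.
#' @return an object of class `"calibration"`: list with `fit_points`,
#'   `bandwidth`, `score_grid` (matrix `N` x `W` of mean F-measures) and
#'   `mode = "f_measure"`.
#' @export
calibrate_grid <- function(images, truths, class_count = 2L, case_id = 1L,
                           polarity = "bright",
                           n_range = 3:60, w_range = 2:50) {
  if (!is.list(images) || !is.list(truths) || !length(images) ||
      length(images) != length(truths))
    stop2("images and truths must be nonempty lists of equal length")
  grid <- matrix(0, length(n_range), length(w_range),
                 dimnames = list(n_range, w_range))
  # the histogram is fixed per image; smoothing depends only on W and the
  # SDD only on (N, W), so precompute per image and bandwidth
  imgs <- lapply(images, rescale_to_255)
  hists <- lapply(imgs, normalized_histogram)
  for (wi in seq_along(w_range)) {
    smooths <- lapply(hists, dft_lowpass, bandwidth = w_range[wi])
    for (ni in seq_along(n_range)) {
      f <- 0
      for (k in seq_along(imgs)) {
        f <- f + tryCatch({
          sdd <- slope_difference(smooths[[k]], n_range[ni])
          pk <- select_real_peaks(sdd, class_count)
          th <- select_threshold(sdd, pk, smooths[[k]], case_id)
          f_measure(binarize(imgs[[k]], th$threshold, polarity), truths[[k]])
        }, error = function(e) 0)
      }
      grid[ni, wi] <- f / length(imgs)
    }
  }
  best <- which(grid == max(grid), arr.ind = TRUE)
  best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
  structure(list(
    fit_points = n_range[best[1]],
    bandwidth = w_range[best[2]],
    score_grid = grid,
    mode = "f_measure"
  ), class = "calibration")
}

#' Benchmark-free calibration by peak counting
#'
#' When no ground truth is available, the fit-point count `N` is tuned using
#' the peak-suppression property of the slope difference distribution:
#' starting from the defaults `N = 15`, `W = 10`, `N` is increased until the
#' SDD shows exactly `class_count` dominant peaks (a large `N` merges or
#' suppresses spurious small peaks).
#'
#' @param image numeric matrix.
#' @param class_count known number of pixel classes `K_c >= 2`.
#' @param bandwidth DFT bandwidth held fixed during the scan; default 10.
#' @param start first `N` tried; default 15.
#' @param frac dominance fraction for [classify_extrema()]; default 0.25.
#' @param rescale rescale the image with [rescale_to_255()] first (default
#'   TRUE; set FALSE for images already on the integer `[0, 255]` scale whose
#'   gray levels should be preserved).
#' @return a `"calibration"` object with `mode = "rational"` and the scanned
#'   peak counts in `peak_counts`.
#' @export
calibrate_rational <- function(image, class_count, bandwidth = 10L,
                               start = 15L, frac = 0.25, rescale = TRUE) {
  kc <- as.integer(class_count)
  if (is.na(kc) || kc < 2L) stop2("class_count must be >= 2")
  img <- if (rescale) rescale_to_255(image) else image
  sm <- dft_lowpass(normalized_histogram(img), bandwidth)
  counts <- integer(0)
  for (n in start:60) {
    sdd <- slope_difference(sm, n)
    np <- nrow(classify_extrema(sdd, frac)$peaks)
    counts[as.character(n)] <- np
    if (np == kc) {
      return(structure(list(
        fit_points = n, bandwidth = as.integer(bandwidth),
        peak_counts = counts, mode = "rational"
      ), class = "calibration"))
    }
  }
  stop2("no N in [", start, ", 60] yields exactly ", kc,
        " dominant peaks (counts ranged over ",
        paste(range(counts), collapse = "-"), ")")
}

#' @export
print.calibration <- function(x, ...) {
  cat("SDD calibration (", x$mode, "): N =", x$fit_points,
      ", W =", x$bandwidth, "\n")
  invisible(x)
}
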