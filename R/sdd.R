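#' Slope difference distribution of a smoothed histogram
#'
#' At each gray level `i` two straight lines are least-squares fitted to the
#' `N` histogram points immediately left of `i` and the `N` points immediately
#' right of `i`; the slope difference is `s(i) = a1(i) - a2(i)` (left slope
#' minus right slope).  A mode of the histogram — rising on the left, falling
#' on the right — is then a positive local maximum of `s`, so SDD *peaks* mark
#' intensity cluster centers, while SDD *valleys* (negative local minima) mark
#' the shoulders between a cluster and the flat background of the histogram,
#' i.e. candidate thresholds.
#'
#' `s` is defined on gray levels `N + 1, ..., 255 - N`.  Local extrema are
#' located at discrete sign changes of `s(i + 1) - s(i)`; on a flat plateau
#' the leftmost index is reported.
#'
#' @param smoothed numeric vector of length 256, typically the output of
#'   [dft_lowpass()] on a [normalized_histogram()].
#' @param fit_points integer `N` in `[3, 60]`, the number of points fitted on
#'   each side.
#' @return an object of class `"sdd"`: a list with elements `s` (numeric
#'   vector), `position` (gray levels where `s` is defined), `fit_points`,
#'   and data frames `peaks` and `valleys` with columns `position`,
#'   `magnitude`.
#' @seealso [select_real_peaks()], [select_threshold()], [sdd_threshold()]
#' @export
slope_difference <- function(smoothed, fit_points) {
  if (length(smoothed) != 256L) stop2("smoothed must have length 256")
  n <- as.integer(fit_points)
  if (is.na(n) || n < 3L || n > 60L) stop2("fit_points must be in [3, 60]")
  # slope of a window of n consecutive points = centered-weight dot product
  wts <- (seq_len(n) - (n + 1) / 2)
  wts <- wts / sum(wts^2)
  # y[t] = slope of the window ending at index t
  y <- stats::filter(smoothed, rev(wts), method = "convolution", sides = 1)
  y <- as.numeric(y)
  pos <- (n + 1L):(255L - n)             # gray levels where s is defined
  a1 <- y[pos]                           # window: levels i-N .. i-1
  a2 <- y[pos + n + 1L]                  # window: levels i+1 .. i+N
  s <- a1 - a2
  ext <- find_extrema(s)
  structure(list(
    s = s,
    position = pos,
    fit_points = n,
    peaks = data.frame(position = pos[ext$peaks], magnitude = s[ext$peaks]),
    valleys = data.frame(position = pos[ext$valleys], magnitude = s[ext$valleys])
  ), class = "sdd")
}

# local maxima/minima of a numeric vector via sign changes of the forward
# difference; plateaus resolve to their leftmost index
find_extrema <- function(s) {
  d <- diff(s)
  sg <- sign(d)
  nz <- which(sg != 0)
  peaks <- integer(0); valleys <- integer(0)
  if (length(nz) >= 2) {
    for (k in seq_len(length(nz) - 1L)) {
      a <- sg[nz[k]]; b <- sg[nz[k + 1L]]
      if (a > 0 && b < 0) peaks <- c(peaks, nz[k] + 1L)
      if (a < 0 && b > 0) valleys <- c(valleys, nz[k] + 1L)
    }
  }
  list(peaks = peaks, valleys = valleys)
}

#' @export
print.sdd <- function(x, ...) {
  cat("Slope difference distribution (N =", x$fit_points, ")\n")
  cat("  defined on gray levels", min(x$position), "-", max(x$position), "\n")
  cat("  ", nrow(x$peaks), "peaks,", nrow(x$valleys), "valleys detected\n")
  invisible(x)
}

#' Classify SDD extrema into real and pseudo by magnitude
#'
#' DFT smoothing of histograms with long flat stretches introduces small
#' harmonic ripples whose SDD extrema ("pseudo" peaks/valleys) are much
#' smaller in magnitude than the extrema produced by actual intensity
#' clusters.  A peak is kept as real when its magnitude is positive and at
#' least `frac` of the largest peak magnitude; a valley when its magnitude is
#' negative with absolute value at least `frac` of the largest valley
#' magnitude.
#'
#' The default `frac = 0.25` sits just above the first-sidelobe ratio of the
#' rectangular (Dirichlet) spectral window (~0.22), the worst-case relative
#' amplitude of the ripples that hard truncation of the DFT spectrum can
#' impress on a flat histogram stretch next to a dominant spike; harmonics
#' therefore always fall below the cut while extrema of comparable clusters
#' stay above it.
#'
#' @param sdd an `"sdd"` object.
#' @param frac dominance fraction in `(0, 1)`; default 0.25.
#' @return list with data frames `peaks` and `valleys` (the real ones).
#' @export
classify_extrema <- function(sdd, frac = 0.25) {
  stopifnot(inherits(sdd, "sdd"))
  if (!(frac > 0 && frac < 1)) stop2("frac must be in (0, 1)")
  pk <- sdd$peaks[sdd$peaks$magnitude > 0, , drop = FALSE]
  if (nrow(pk)) pk <- pk[pk$magnitude >= frac * max(pk$magnitude), , drop = FALSE]
  vl <- sdd$valleys[sdd$valleys$magnitude < 0, , drop = FALSE]
  if (nrow(vl)) vl <- vl[-vl$magnitude >= frac * max(-vl$magnitude), , drop = FALSE]
  list(peaks = pk, valleys = vl)
}

#' Select the real peaks of an SDD for a known class count
#'
#' Peaks are ranked by magnitude; the largest `class_count` are the real
#' peaks (the intensity cluster centers), returned in ascending position
#' order.
#'
#' @param sdd an `"sdd"` object.
#' @param class_count integer `K_c >= 2` (or 1 for a unimodal histogram).
#' @return numeric vector of `class_count` peak positions, ascending.
#' @export
select_real_peaks <- function(sdd, class_count) {
  stopifnot(inherits(sdd, "sdd"))
  kc <- as.integer(class_count)
  if (is.na(kc) || kc < 1L) stop2("class_count must be a positive integer")
  pk <- sdd$peaks
  if (nrow(pk) < kc)
    stop2("only ", nrow(pk), " SDD peaks detected but class_count = ", kc,
          "; the fit-point count N may have suppressed peaks - recalibrate")
  pk <- pk[order(-pk$magnitude), , drop = FALSE][seq_len(kc), , drop = FALSE]
  sort(pk$position)
}

#' Select a threshold from the SDD valleys
#'
#' Identifies the background class as the real peak nearest the histogram
#' mode (backgrounds dominate the pixel count), then returns the deepest
#' valley strictly between the two real peaks that bound the requested
#' separation:
#' * `case_id = 1` separates the background from the adjacent object class
#'   (when the background peak is interior, the side holding more real peaks);
#' * `case_id = m >= 2` separates object class `m - 1` from object class `m`
#'   in ascending intensity order.
#'
#' @param sdd an `"sdd"` object.
#' @param real_peaks ascending peak positions from [select_real_peaks()].
#' @param smoothed the smoothed histogram the SDD was computed from.
#' @param case_id which separation to extract (see Details); default 1.
#' @return an object of class `"sdd_threshold"`: list with `threshold`,
#'   `real_peaks`, `valley` (position + magnitude), `bounds`, `case_id`,
#'   `sdd`, `smoothed`.
#' @export
select_threshold <- function(sdd, real_peaks, smoothed, case_id = 1L) {
  stopifnot(inherits(sdd, "sdd"))
  if (length(smoothed) != 256L) stop2("smoothed must have length 256")
  kc <- length(real_peaks)
  case_id <- as.integer(case_id)
  if (is.na(case_id) || case_id < 1L || case_id > kc - 1L)
    stop2("case_id must be in [1, ", kc - 1L, "] for ", kc, " classes")
  real_peaks <- sort(real_peaks)
  mode_bin <- which.max(smoothed) - 1L
  bg_idx <- which.min(abs(real_peaks - mode_bin))

  if (case_id == 1L) {
    n_below <- bg_idx - 1L
    n_above <- kc - bg_idx
    if (n_above > n_below)      bounds <- real_peaks[c(bg_idx, bg_idx + 1L)]
    else if (n_below > n_above) bounds <- real_peaks[c(bg_idx - 1L, bg_idx)]
    else stop2("background peak is interior with equally many object peaks ",
               "on both sides; Case 1 is ambiguous")
  } else {
    obj <- real_peaks[-bg_idx]
    if (case_id > length(obj))
      stop2("case_id = ", case_id, " requires at least ", case_id,
            " object classes")
    bounds <- sort(obj[c(case_id - 1L, case_id)])
  }

  vl <- sdd$valleys
  vl <- vl[vl$position > bounds[1] & vl$position < bounds[2], , drop = FALSE]
  if (!nrow(vl))
    stop2("no SDD valley between the bounding peaks at ", bounds[1], " and ",
          bounds[2], "; recalibrate N / W")
  best <- vl[which.min(vl$magnitude), ]
  structure(list(
    threshold = best$position,
    real_peaks = real_peaks,
    valley = best,
    bounds = bounds,
    case_id = case_id,
    sdd = sdd,
    smoothed = smoothed
  ), class = "sdd_threshold")
}

#' @export
print.sdd_threshold <- function(x, ...) {
  cat("SDD threshold:", x$threshold, "\n")
  cat("  real peaks at", paste(x$real_peaks, collapse = ", "),
      " (case", x$case_id, "between", x$bounds[1], "and", x$bounds[2], ")\n")
  invisible(x)
}

#' Threshold selection from an image via the slope difference distribution
#'
#' End-to-end convenience wrapper: rescale the image to `[0, 255]`, build the
#' max-normalized histogram, smooth it with the low-pass DFT filter, compute
#' the slope difference distribution, pick the `class_count` largest peaks as
#' cluster centers, and return the deepest valley between the peaks bounding
#' the requested separation case.
#'
#' @param image numeric matrix of non-negative intensities.
#' @param class_count number of pixel classes `K_c`; default 2 (background +
#'   one object class).
#' @param case_id which separation to extract; default 1 (background vs
#'   objects).  See [select_threshold()].
#' @param fit_points line-fit count `N` in `[3, 60]`; default 15.
#' @param bandwidth DFT bandwidth `W` in `[1, 128]`; default 10.
#' @param rescale rescale the image with [rescale_to_255()] first
#'   (default TRUE; set FALSE if the image is already integer `[0, 255]`).
#' @return an `"sdd_threshold"` object (see [select_threshold()]); the
#'   `raw_histogram` element carries the unsmoothed normalized histogram for
#'   diagnostics.
#' @examples
#' img <- matrix(50, 64, 64); img[20:40, 20:40] <- 200
#' th <- sdd_threshold(img)
#' th$threshold
#' @export
sdd_threshold <- function(image, class_count = 2L, case_id = 1L,
                          fit_points = 15L, bandwidth = 10L, rescale = TRUE) {
  if (rescale) image <- rescale_to_255(image)
  p <- normalized_histogram(image)
  sm <- dft_lowpass(p, bandwidth)
  sdd <- slope_difference(sm, fit_points)
  peaks <- select_real_peaks(sdd, class_count)
  res <- select_threshold(sdd, peaks, sm, case_id)
  res$raw_histogram <- p
  res$bandwidth <- as.integer(bandwidth)
  res
}
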