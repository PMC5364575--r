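#' Rescale an image to the integer range \[0, 255\]
#'
#' Linearly maps a non-negative image onto `[0, 255]` by
#' `round(255 * I / max(I))`, with half-way values rounded up.  All histogram
#' operations in the package work on images rescaled this way.
#'
#' @param image numeric matrix of non-negative intensities with `max > 0`.
#' @return integer-valued numeric matrix in `[0, 255]` with maximum 255.
#' @examples
#' rescale_to_255(matrix(c(10, 20, 40), 1))
#' @export
rescale_to_255 <- function(image) {
  assert_image(image)
  mx <- max(image)
  if (mx <= 0) stop2("cannot rescale an all-zero image")
  round_half_up(255 * image / mx)
}

#' Max-normalized 256-bin histogram
#'
#' Bin frequencies of an integer image in `[0, 255]`, divided by the largest
#' bin count so that the modal bin has value exactly 1.
#'
#' @param image integer-valued numeric matrix in `[0, 255]` (see
#'   [rescale_to_255()]).
#' @return numeric vector of length 256 (`P[m + 1]` is the normalized
#'   frequency of gray level `m`), maximum exactly 1.
#' @export
normalized_histogram <- function(image) {
  assert_image(image)
  if (max(image) > 255 || any(image != floor(image)))
    stop2("image must be integer-valued in [0, 255]; apply rescale_to_255() first")
  counts <- tabulate(as.integer(image) + 1L, nbins = 256L)
  counts / max(counts)
}

#' Low-pass DFT filter for a length-256 signal
#'
#' Forward length-256 DFT, retention of the `W + 1` lowest-frequency
#' coefficients (and their conjugate mirror `256 - W, ..., 255`), inverse DFT,
#' and pointwise magnitude.  `W = 128` retains the full band and reproduces a
#' non-negative input to numerical tolerance.
#'
#' @param signal numeric vector of length 256.
#' @param bandwidth integer `W` in `[1, 128]`, the number of positive
#'   frequencies kept.
#' @return numeric vector of length 256, the smoothed signal.
#' @export
dft_lowpass <- function(signal, bandwidth) {
  if (length(signal) != 256L) stop2("signal must have length 256")
  w <- as.integer(bandwidth)
  if (is.na(w) || w < 1L || w > 128L) stop2("bandwidth must be in [1, 128]")
  f <- stats::fft(signal)
  keep <- logical(256L)
  keep[1:(w + 1L)] <- TRUE          # k = 0 .. W
  keep[(256L - w + 1L):256L] <- TRUE # k = 256-W .. 255
  f[!keep] <- 0
  Mod(stats::fft(f, inverse = TRUE)) / 256
}
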