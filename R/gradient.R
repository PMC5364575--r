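#' Sobel gradient magnitude
#'
#' Computes the gradient-magnitude image `sqrt(Ix^2 + Iy^2)` from the two
#' classic 3x3 Sobel responses along rows and columns.  Borders are handled by
#' replicate-edge padding so a flat image border does not produce spurious
#' edges; the integer kernels are used without normalization (the gradient
#' image is rescaled to \[0, 255\] before its histogram is thresholded, so the
#' absolute scale is immaterial).
#'
#' @param image numeric matrix of non-negative intensities, at least 3x3.
#' @return numeric matrix of gradient magnitudes, same shape as `image`;
#'   all-zero for a constant input.
#' @examples
#' img <- matrix(0, 16, 16); img[, 9:16] <- 255
#' g <- sobel_gradient(img)
#' range(g[, c(1:6, 11:16)])  # zero away from the step
#' @export
sobel_gradient <- function(image) {
  assert_image(image)
  if (nrow(image) < 3 || ncol(image) < 3)
    stop2("image must be at least 3x3 for the Sobel operator")
  p <- pad_replicate(image, 1L)
  h <- nrow(image); w <- ncol(image)
  at <- function(dr, dc) p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  # difference across columns (vertical edges) and across rows
  gx <- (at(-1, -1) + 2 * at(0, -1) + at(1, -1)) -
        (at(-1,  1) + 2 * at(0,  1) + at(1,  1))
  gy <- (at(-1, -1) + 2 * at(-1, 0) + at(-1, 1)) -
        (at( 1, -1) + 2 * at( 1, 0) + at( 1, 1))
  sqrt(gx^2 + gy^2)
}
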