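#' Binarize an image at a threshold
#'
#' With `polarity = "bright"` (the default) a pixel is foreground when its
#' value is `>= threshold`; with `polarity = "dark"` the comparison is
#' inverted (`< threshold`), for images whose cells are darker than the
#' background.
#'
#' @param image numeric matrix.
#' @param threshold gray level in `[0, 255]` (an `"sdd_threshold"` object is
#'   also accepted).
#' @param polarity `"bright"` or `"dark"`.
#' @return logical matrix.
#' @export
binarize <- function(image, threshold, polarity = c("bright", "dark")) {
  assert_image(image)
  polarity <- match.arg(polarity)
  if (inherits(threshold, "sdd_threshold")) threshold <- threshold$threshold
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 255)
    stop2("threshold must be a single value in [0, 255]")
  if (polarity == "bright") image >= threshold else image < threshold
}

#' Union segmentation of intensity and gradient masks
#'
#' Combines the intensity mask `S_I` and the gradient (edge) mask `S_g`
#' according to the image case:
#' * **Case 1** — cells touch and their edges are open curves:
#'   `S_u = S_I & !S_g` (the edge mask carves boundaries into the intensity
#'   mask);
#' * **Case 2** — every cell has a closed edge contour: `S_u = !S_g`
#'   (the intensity mask is not needed);
#' * **Case 3** — cells are mostly isolated: `S_u = S_I`.
#'
#' @param s_i logical matrix, intensity segmentation.
#' @param s_g logical matrix, gradient segmentation; may be `NULL` for
#'   case 3.
#' @param case_id 1, 2 or 3.
#' @return logical matrix `S_u`.
#' @export
union_masks <- function(s_i, s_g, case_id) {
  case_id <- as.integer(case_id)
  if (!case_id %in% 1:3) stop2("case_id must be 1, 2 or 3")
  if (case_id == 3L) {
    assert_mask(s_i)
    return(s_i)
  }
  assert_mask(s_g)
  if (case_id == 2L) return(!s_g)
  assert_mask(s_i)
  if (!identical(dim(s_i), dim(s_g)))
    stop2("s_i and s_g must have the same shape")
  s_i & !s_g
}
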