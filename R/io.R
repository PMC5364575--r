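#' Read a single-channel image
#'
#' Reads a TIFF or PNG file into a numeric matrix on the `[0, 255]` scale.
#' Multi-channel images are refused unless `to_gray = "luminance"`, which
#' converts with the Rec. 709 weights (0.2126 R + 0.7152 G + 0.0722 B).
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @param to_gray `"refuse"` (default) or `"luminance"`.
#' @return numeric matrix.
#' @export
read_gray_image <- function(path, to_gray = c("refuse", "luminance")) {
  to_gray <- match.arg(to_gray)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop2("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) {
    if (to_gray == "refuse")
      stop2("multi-channel image; pass to_gray = \"luminance\" to convert")
    img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
  }
  img * 255
}

#' Write a mask or image
#'
#' Masks are written as 8-bit 0/255 images; label matrices as 16-bit TIFF.
#'
#' @param x logical mask, numeric image in `[0, 255]`, or integer label
#'   matrix (for `write_label_image`).
#' @param path output path (`.tif`/`.tiff` or `.png` for masks and images;
#'   TIFF only for labels).
#' @export
write_gray_image <- function(x, path) {
  if (is.logical(x)) x <- x * 255
  x <- pmin(pmax(x, 0), 255) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    png = png::writePNG(x, path),
    stop2("unsupported image format: .", ext))
  invisible(path)
}

#' @rdname write_gray_image
#' @export
write_label_image <- function(x, path) {
  if (max(x) > 65535) stop2("more than 65535 labels")
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write and read centroid tables
#'
#' CSV with columns `cell_id`, `row`, `col`, `seed_area`, `iteration`;
#' coordinates are 0-based `(row, col)` pixel centers.
#'
#' @param centroids data frame from [seed_centroids()].
#' @param path CSV path.
#' @export
write_centroids <- function(centroids, path) {
  utils::write.csv(centroids, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  utils::read.csv(path)
}

#' Read and write pipeline configuration files
#'
#' Configurations are stored as YAML; see [pipeline_config()] for the keys.
#'
#' @param config a `"pipeline_config"` object.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
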