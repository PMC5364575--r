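#' Binary erosion and dilation with the radius-1 diamond element
#'
#' The structuring element is the 4-connected radius-1 disk (the 5-point
#' diamond: a pixel and its 4 edge neighbors).  Erosion keeps a pixel when
#' every translate of the element lies inside the mask — pixels outside the
#' image count as background, per the set definition.  Dilation is the dual.
#'
#' @param mask logical matrix.
#' @param times number of repetitions; default 1.
#' @return logical matrix of the same shape.
#' @export
erode_diamond <- function(mask, times = 1L) {
  assert_mask(mask)
  for (i in seq_len(times)) {
    mask <- mask &
      shift_matrix(mask, 1L, 0L, FALSE) & shift_matrix(mask, -1L, 0L, FALSE) &
      shift_matrix(mask, 0L, 1L, FALSE) & shift_matrix(mask, 0L, -1L, FALSE)
  }
  mask
}

#' @rdname erode_diamond
#' @export
dilate_diamond <- function(mask, times = 1L) {
  assert_mask(mask)
  for (i in seq_len(times)) {
    mask <- mask |
      shift_matrix(mask, 1L, 0L, FALSE) | shift_matrix(mask, -1L, 0L, FALSE) |
      shift_matrix(mask, 0L, 1L, FALSE) | shift_matrix(mask, 0L, -1L, FALSE)
  }
  mask
}

#' Noise blob removing filter
#'
#' Morphological opening: `repeats` erosions with the radius-1 diamond
#' element followed by `repeats` dilations with the same element.
#' Threadlike blobs of half-width below `repeats` are eliminated while
#' massive blobs are restored; the output is always a subset of the input and
#' the filter is idempotent.
#'
#' @param mask logical matrix, the union segmentation.
#' @param repeats number of erosion (and dilation) passes `N_l >= 1`;
#'   default 3.
#' @return logical matrix of the same shape.
#' @export
noise_blob_filter <- function(mask, repeats = 3L) {
  assert_mask(mask)
  nl <- as.integer(repeats)
  if (is.na(nl) || nl < 1L) stop2("repeats must be >= 1")
  dilate_diamond(erode_diamond(mask, nl), nl)
}

#' Label connected components of a binary mask
#'
#' Components are found on the pixel-adjacency graph (via
#' [igraph::components()]); labels are assigned in raster order of each
#' component's first pixel, so labelling is deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix; 0 is background, components are numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  if (!connectivity %in% c(4L, 8L)) stop2("connectivity must be 4 or 8")
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  idx <- which(mask)
  if (!length(idx)) return(out)
  vid <- matrix(0L, h, w)
  vid[idx] <- seq_along(idx)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- integer(0)
  for (o in offs) {
    nb <- shift_matrix(vid, o[1], o[2], 0L)
    both <- which(mask & nb > 0L)
    if (length(both)) edges <- c(edges, rbind(vid[both], nb[both]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  mem <- igraph::components(g)$membership
  # idx is in column-major raster order, so first-occurrence relabelling
  # numbers components deterministically by their first pixel
  out[idx] <- match(mem, unique(mem))
  out
}

# pixel areas of each label in a label matrix
component_areas <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}
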