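#' Three-class test image
#'
#' A flat background with two flat elliptical objects at higher gray levels —
#' the canonical fixture for demonstrating slope-difference-distribution
#' threshold selection on a trimodal histogram.  The noiseless image has
#' exactly three nonzero histogram bins; [add_gaussian_noise()] and
#' [iterative_blur()] derive the noisy and blurred variants.
#'
#' @param shape `c(rows, cols)`; default `c(256, 256)`.
#' @param levels three strictly increasing gray levels in `[0, 255]`:
#'   background, dark object, bright object; default `c(50, 120, 220)`.
#' @param objects list of two object descriptors, each a list with `center`
#'   `(row, col)`, `radii` `(row, col)` half-sizes and optional `kind`
#'   (`"rect"` or `"ellipse"`, default `"rect"`); `NULL` for the defaults —
#'   two large rectangular patches each covering roughly 27% of the image,
#'   so that every class contributes a histogram spike of comparable height
#'   and the real slope-difference extrema dominate the smoothing harmonics.
#' @return list with `image` (numeric matrix) and `truth` (list with integer
#'   `labels` — 0 background, 1 dark object, 2 bright object — and the
#'   per-class pixel counts `class_areas`).
#' @export
make_three_class <- function(shape = c(256L, 256L),
                             levels = c(50, 120, 220),
                             objects = NULL) {
  if (length(levels) != 3 || any(diff(levels) <= 0) ||
      min(levels) < 0 || max(levels) > 255)
    stop2("levels must be three strictly increasing values in [0, 255]")
  if (is.null(objects)) {
    objects <- list(
      list(center = shape * c(0.27, 0.50), radii = shape * c(0.18, 0.38)),
      list(center = shape * c(0.74, 0.50), radii = shape * c(0.18, 0.38)))
  }
  img <- matrix(levels[1], shape[1], shape[2])
  labels <- matrix(0L, shape[1], shape[2])
  for (k in seq_along(objects)) {
    ob <- objects[[k]]
    m <- if (identical(ob$kind, "ellipse"))
      ellipse_mask(shape, ob$center, ob$radii)
    else rect_mask(shape, ob$center, ob$radii)
    img[m] <- levels[k + 1]
    labels[m] <- k
  }
  list(image = img,
       truth = list(labels = labels,
                    class_areas = tabulate(labels + 1L, nbins = 3L)))
}

# pixels inside an axis-aligned rectangle of given center and half-sizes
rect_mask <- function(shape, center, radii) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - center[2]
  abs(r) <= radii[1] & abs(c) <= radii[2]
}

# pixels inside an axis-aligned ellipse, optionally with a radial sinusoid
# perturbation of the boundary (amplitude in pixels) and phase offset
ellipse_mask <- function(shape, center, radii, rough_amp = 0,
                         rough_waves = 0, phase = 0) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2]) - center[1]
  c <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - center[2]
  rho <- sqrt((r / radii[1])^2 + (c / radii[2])^2)
  if (rough_amp > 0) {
    theta <- atan2(c, r)
    rho <= 1 + (rough_amp / mean(radii)) * sin(rough_waves * theta + phase)
  } else rho <= 1
}

#' Add clipped Gaussian noise to an image
#'
#' @param image numeric matrix.
#' @param sigma noise standard deviation in gray levels; 0 returns the image
#'   unchanged.
#' @param seed optional integer; when given, the global RNG state is left
#'   untouched and the output is reproducible.
#' @return numeric matrix, rounded and clipped to `[0, 255]`.
#' @export
add_gaussian_noise <- function(image, sigma, seed = NULL) {
  assert_image(image)
  if (sigma < 0) stop2("sigma must be >= 0")
  if (sigma == 0) return(image)
  with_seed(seed, {
    out <- image + matrix(stats::rnorm(length(image), 0, sigma), nrow(image))
    round_half_up(pmin(pmax(out, 0), 255))
  })
}

#' Iterative moving-average blur
#'
#' Repeated convolution with a normalized `window` x `window` box kernel,
#' replicate borders — the blur used to derive the third synthetic test
#' image from the noisy one.
#'
#' @param image numeric matrix.
#' @param window odd box width; default 5.
#' @param passes number of passes; 0 returns the image unchanged.
#' @return numeric matrix.
#' @export
iterative_blur <- function(image, window = 5L, passes = 10L) {
  assert_image(image)
  w <- as.integer(window)
  if (is.na(w) || w < 1L || w %% 2L == 0L) stop2("window must be a positive odd integer")
  k <- w %/% 2L
  box <- rep(1 / w, w)
  for (p in seq_len(passes)) {
    pad <- pad_replicate(image, k)
    pad <- stats::filter(pad, box, sides = 2)            # down columns
    pad <- t(stats::filter(t(pad), box, sides = 2))      # across rows
    image <- pad[(k + 1):(k + nrow(image)), (k + 1):(k + ncol(image))]
  }
  image
}

#' Synthetic cell-field image with ground truth
#'
#' Renders bright, slightly roughened circular cells on a dark background,
#' together with the artifacts the optional pipeline filters exist to
#' handle: touching cell pairs (merged into one connected component),
#' threadlike noise blobs at cell intensity, high-frequency boundary
#' roughness, and interior holes.  Ground-truth labels always describe the
#' intact cells: holes and noise blobs are imaging artifacts, not truth.
#'
#' Cell sizes are stratified by role, reflecting the interplay between the
#' area gate of the iterative-erosion quantifier (the mean component area
#' after a few erosions) and the defects each optional filter repairs:
#' * *plain singles* are the small cells; long threadlike noise inflates the
#'   automatic shape-noise threshold `T_sn` past their contour length, so
#'   they are lost when the noise-blob filter is disabled;
#' * *touching pairs* are the largest blobs, so the merged component stays
#'   above the area gate until erosion severs the contact neck and each
#'   member yields its own seed;
#' * *vacuole cells* are large cells carrying a central dark vacuole with a
#'   bright core blob inside it.  The core's short contour falls below the
#'   automatic shape-noise threshold, so the boundary filter deletes it; if
#'   that filter is disabled the core survives as a small component inside
#'   the truth region and is harvested as a spurious second seed.
#'
#' @param shape `c(rows, cols)`; default `c(384, 384)`.
#' @param n_cells total number of cells; default 20.
#' @param touching_pairs number of touching pairs among them; default 4.
#' @param radius_single,radius_pair,radius_hole radius ranges (px) for the
#'   three cell roles; defaults `c(6.5, 7.5)`, `c(16.5, 17.5)`, `c(15, 16)`.
#' @param bg_level,cell_level background and cell gray levels; defaults 40
#'   and 200.
#' @param noise_blobs number of threadlike noise polylines; default 12.
#' @param blob_segments,blob_step polyline segment count and length;
#'   defaults 16 and 80.
#' @param roughness_amplitude boundary roughness in pixels (capped at 20% of
#'   each cell's radius; touching pairs are rendered smooth so their contact
#'   neck is clean); default 2.
#' @param roughness_waves sinusoid wave count around each cell; default 13.
#' @param n_hole_cells,hole_radius,hole_core_radius vacuole placement: number
#'   of cells with a central vacuole, the vacuole radius and the radius of
#'   the bright core inside it; defaults 4, 6 and 3.5.
#' @param noise_sigma Gaussian intensity noise; default 3 (high-contrast
#'   fluorescent imagery; keeps the background a comfortable five standard
#'   deviations below the selected threshold, so thresholding artifacts are
#'   limited to the structures the generator places deliberately).
#' @param seed optional integer for bit-reproducible output.
#' @return list with `image` (numeric matrix) and `truth`: a list with
#'   `labels` (integer matrix, one id per cell), `centroids` (data frame
#'   `cell_id`, `row`, `col`, 0-based), `region_mask` (cells union),
#'   `edge_band` (cell contours dilated by 1 px).
#' @export
make_cell_field <- function(shape = c(384L, 384L), n_cells = 20L,
                            touching_pairs = 4L,
                            radius_single = c(6.5, 7.5),
                            radius_pair = c(16.5, 17.5),
                            radius_hole = c(15, 16),
                            bg_level = 40, cell_level = 200,
                            noise_blobs = 12L, blob_segments = 16L,
                            blob_step = 80, roughness_amplitude = 2,
                            roughness_waves = 13L, n_hole_cells = 4L,
                            hole_radius = 6, hole_core_radius = 3.5,
                            noise_sigma = 3, seed = NULL) {
  n_single <- n_cells - 2L * touching_pairs - n_hole_cells
  if (n_single < 0)
    stop2("n_cells too small for the requested pairs and hole cells")
  with_seed(seed, {
    spread <- function(rng, k) if (k > 0)
      seq(rng[1], rng[2], length.out = max(k, 2))[seq_len(k)] *
        stats::runif(k, 0.98, 1.02) else numeric(0)
    radii <- c(spread(radius_single, n_single),
               spread(radius_pair, 2L * touching_pairs),
               spread(radius_hole, n_hole_cells))
    single_ids <- seq_len(n_single)
    pair_ids <- if (touching_pairs > 0)
      n_single + seq_len(2L * touching_pairs) else integer(0)
    hole_ids <- if (n_hole_cells > 0)
      n_single + 2L * touching_pairs + seq_len(n_hole_cells) else integer(0)

    centers <- place_cells(shape, radii, pair_ids)

    labels <- matrix(0L, shape[1], shape[2])
    rho_best <- matrix(Inf, shape[1], shape[2])
    phases <- stats::runif(n_cells, 0, 2 * pi)
    rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    for (i in seq_len(n_cells)) {
      dr <- rr - centers[i, 1]; dc <- cc - centers[i, 2]
      rho <- sqrt(dr^2 + dc^2) / radii[i]
      theta <- atan2(dc, dr)
      amp <- if (i %in% pair_ids) 0 else
        min(roughness_amplitude, 0.2 * radii[i])
      lim <- 1 + (amp / radii[i]) *
        sin(roughness_waves * theta + phases[i])
      inside <- rho <= lim & rho < rho_best
      labels[inside] <- i
      rho_best[inside] <- rho[inside]
    }
    region <- labels > 0L

    # central vacuoles with bright cores (artifacts, absent from the truth)
    holes <- matrix(FALSE, shape[1], shape[2])
    cores <- matrix(FALSE, shape[1], shape[2])
    for (i in hole_ids) {
      holes <- holes | ellipse_mask(shape, centers[i, ],
                                    c(hole_radius, hole_radius))
      cores <- cores | ellipse_mask(shape, centers[i, ],
                                    c(hole_core_radius, hole_core_radius))
    }
    holes <- holes & region

    # threadlike noise polylines, kept clear of the cells
    threads <- matrix(FALSE, shape[1], shape[2])
    if (noise_blobs > 0) {
      keep_out <- dilate_diamond(region, 2L)
      for (b in seq_len(noise_blobs)) {
        pos <- c(stats::runif(1, 10, shape[1] - 10),
                 stats::runif(1, 10, shape[2] - 10))
        ang <- stats::runif(1, 0, 2 * pi)
        for (s in seq_len(blob_segments)) {
          nxt <- pos + blob_step * c(cos(ang), sin(ang))
          nxt <- pmin(pmax(nxt, 3), shape - 3)
          t <- seq(0, 1, length.out = 2L * ceiling(blob_step) + 1L)
          px <- round_half_up(cbind(pos[1] + t * (nxt[1] - pos[1]),
                                    pos[2] + t * (nxt[2] - pos[2])))
          threads[px] <- TRUE
          pos <- nxt
          ang <- ang + stats::runif(1, -pi / 3, pi / 3)
        }
      }
      threads <- threads | shift_matrix(threads, 0L, 1L, FALSE) |
        shift_matrix(threads, 1L, 0L, FALSE)          # thickness 2
      threads <- threads & !keep_out
    }

    img <- matrix(bg_level, shape[1], shape[2])
    img[(region & !holes) | cores | threads] <- cell_level
    img <- add_gaussian_noise(img, noise_sigma)

    # truth tables
    cent <- seed_centroids(labels)[, c("cell_id", "row", "col")]
    interior <- region & shift_same(labels)
    contour <- region & !interior
    list(image = img,
         truth = list(labels = labels,
                      centroids = cent,
                      region_mask = region,
                      edge_band = dilate_diamond(contour, 1L)))
  })
}

# TRUE where all 4-neighbors carry the same label (padding counts as
# different), i.e. the label-interior pixels
shift_same <- function(labels) {
  same <- matrix(TRUE, nrow(labels), ncol(labels))
  for (o in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)))
    same <- same & (shift_matrix(labels, o[1], o[2], -1L) == labels)
  same
}

# rejection-sample cell centers; singles keep a clear margin from everything,
# consecutive pair members overlap by ~2 px so they form one connected blob
place_cells <- function(shape, radii, pair_ids) {
  n <- length(radii)
  centers <- matrix(NA_real_, n, 2)
  placed <- integer(0)
  clear <- function(pt, rad) {
    if (pt[1] < rad + 4 || pt[1] > shape[1] - rad - 4 ||
        pt[2] < rad + 4 || pt[2] > shape[2] - rad - 4) return(FALSE)
    for (j in placed)
      if (sqrt(sum((pt - centers[j, ])^2)) < rad + radii[j] + 6) return(FALSE)
    TRUE
  }
  pair_first <- pair_ids[seq_along(pair_ids) %% 2L == 1L]
  # place the pairs (largest footprint) first, then the singles
  for (i in c(pair_first, setdiff(seq_len(n), pair_ids))) {
    done <- FALSE
    for (attempt in 1:5000) {
      if (i %in% pair_first) {
        d <- radii[i] + radii[i + 1L] - 0.75
        ang <- stats::runif(1, 0, 2 * pi)
        mid <- c(stats::runif(1, 1, shape[1]), stats::runif(1, 1, shape[2]))
        pt <- mid - (d / 2) * c(cos(ang), sin(ang))
        pt2 <- mid + (d / 2) * c(cos(ang), sin(ang))
        if (clear(pt, radii[i]) && clear(pt2, radii[i + 1L])) {
          centers[i, ] <- pt; centers[i + 1L, ] <- pt2
          placed <- c(placed, i, i + 1L)
          done <- TRUE
        }
      } else {
        pt <- c(stats::runif(1, 1, shape[1]), stats::runif(1, 1, shape[2]))
        if (clear(pt, radii[i])) {
          centers[i, ] <- pt
          placed <- c(placed, i)
          done <- TRUE
        }
      }
      if (done) break
    }
    if (!done) stop2("could not place cells; reduce n_cells or radii")
  }
  centers
}
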