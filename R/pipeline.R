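#' Pipeline configuration
#'
#' Collects every tunable parameter of the segmentation/quantification
#' pipeline with its documented range and default.  `t_sn` and `s0` may be
#' `"auto"` (data-driven: see [boundary_smoothing_filter()] and
#' [estimate_area_threshold()]) or a fixed number.
#'
#' @param class_count pixel classes `K_c >= 2` in the intensity image;
#'   default 2.
#' @param case_id union case 1, 2 or 3 (see [union_masks()]); default 1.
#' @param threshold_case which SDD separation the intensity threshold
#'   extracts (see [select_threshold()]); default 1.
#' @param n_intensity,w_intensity SDD parameters `(N, W)` for the intensity
#'   histogram; defaults 15 and 10.
#' @param n_gradient,w_gradient SDD parameters for the gradient histogram;
#'   defaults 15 and 10.
#' @param polarity `"bright"` if cells are brighter than the background,
#'   `"dark"` otherwise.
#' @param noise_filter,n_l enable the noise blob filter and its repeat count
#'   `N_l`; defaults TRUE, 3.
#' @param boundary_filter,t_sn,w_b enable the boundary smoothing filter, its
#'   length threshold `T_sn` (`"auto"` or a number) and contour bandwidth
#'   `W_b`; defaults TRUE, `"auto"`, 20.  The bandwidth is chosen to
#'   suppress pixel-scale contour noise while preserving the concave necks
#'   between touching cells, which the erosion quantifier needs intact.
#' @param pre_erosions,s0 area-gate estimation erosions and the gate `S_0`
#'   (`"auto"` or a number); defaults 3, `"auto"`.
#' @return an object of class `"pipeline_config"` (a validated named list).
#' @export
pipeline_config <- function(class_count = 2L, case_id = 1L,
                            threshold_case = 1L,
                            n_intensity = 15L, w_intensity = 10L,
                            n_gradient = 15L, w_gradient = 10L,
                            polarity = c("bright", "dark"),
                            noise_filter = TRUE, n_l = 3L,
                            boundary_filter = TRUE, t_sn = "auto",
                            w_b = 20L, pre_erosions = 3L, s0 = "auto") {
  polarity <- match.arg(polarity)
  chk <- function(x, lo, hi, nm) {
    if (!is.numeric(x) || length(x) != 1 || x < lo || x > hi)
      stop2(nm, " must be a single value in [", lo, ", ", hi, "]")
    x
  }
  chk(class_count, 2, 32, "class_count"); chk(case_id, 1, 3, "case_id")
  chk(threshold_case, 1, class_count - 1, "threshold_case")
  chk(n_intensity, 3, 60, "n_intensity"); chk(w_intensity, 1, 128, "w_intensity")
  chk(n_gradient, 3, 60, "n_gradient"); chk(w_gradient, 1, 128, "w_gradient")
  chk(n_l, 1, 50, "n_l"); chk(w_b, 1, 512, "w_b")
  chk(pre_erosions, 0, 50, "pre_erosions")
  if (!identical(t_sn, "auto")) chk(t_sn, 0, Inf, "t_sn")
  if (!identical(s0, "auto")) chk(s0, 1e-9, Inf, "s0")
  structure(list(
    class_count = as.integer(class_count), case_id = as.integer(case_id),
    threshold_case = as.integer(threshold_case),
    n_intensity = as.integer(n_intensity), w_intensity = as.integer(w_intensity),
    n_gradient = as.integer(n_gradient), w_gradient = as.integer(w_gradient),
    polarity = polarity,
    noise_filter = isTRUE(noise_filter), n_l = as.integer(n_l),
    boundary_filter = isTRUE(boundary_filter), t_sn = t_sn,
    w_b = as.integer(w_b), pre_erosions = as.integer(pre_erosions), s0 = s0
  ), class = "pipeline_config")
}

#' Run the full segmentation and quantification pipeline
#'
#' Executes, in order: rescaling to `[0, 255]`, Sobel gradient enhancement,
#' SDD threshold selection for the intensity and (when the union case needs
#' it) the gradient image, binarization, union segmentation, the optional
#' noise blob filter, the optional boundary smoothing filter, and iterative
#' erosion quantification.  The pipeline is a pure function of the image and
#' configuration.
#'
#' @param image numeric matrix or path to a TIFF/PNG file.
#' @param config a [pipeline_config()].
#' @param to_gray forwarded to [read_gray_image()] when `image` is a path.
#' @return an object of class `"sdd_pipeline"`: list with `centroids` (data
#'   frame), `seeds` (`"seed_set"`), `n_cells`, `thresholds` (list with the
#'   `"sdd_threshold"` objects `intensity` and `gradient`, either may be
#'   `NULL`), `masks` (list `s_i`, `s_g`, `s_u`, `filtered`), `s0`, `t_sn`
#'   and `config`.
#' @examples
#' field <- make_cell_field(n_cells = 6, touching_pairs = 0, noise_blobs = 0,
#'                          n_hole_cells = 0, seed = 1)
#' res <- run_pipeline(field$image, pipeline_config(case_id = 3))
#' res$n_cells
#' @export
run_pipeline <- function(image, config = pipeline_config(),
                         to_gray = "refuse") {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(image)) image <- read_gray_image(image, to_gray)
  img <- rescale_to_255(image)

  th_i <- th_g <- NULL
  s_i <- s_g <- NULL
  if (config$case_id %in% c(1L, 3L)) {
    th_i <- sdd_threshold(img, config$class_count, config$threshold_case,
                          config$n_intensity, config$w_intensity,
                          rescale = FALSE)
    s_i <- binarize(img, th_i$threshold, config$polarity)
  }
  if (config$case_id %in% c(1L, 2L)) {
    grad <- rescale_to_255(sobel_gradient(img))
    th_g <- sdd_threshold(grad, 2L, 1L, config$n_gradient, config$w_gradient,
                          rescale = FALSE)
    s_g <- binarize(grad, th_g$threshold, "bright")
  }
  s_u <- union_masks(s_i, s_g, config$case_id)

  filtered <- s_u
  if (config$noise_filter)
    filtered <- noise_blob_filter(filtered, config$n_l)
  t_sn_used <- NA_real_
  if (config$boundary_filter) {
    t_sn <- if (identical(config$t_sn, "auto")) NULL else config$t_sn
    traces <- trace_boundaries(filtered)
    if (length(traces)) {
      if (is.null(t_sn)) {
        outer_len <- vapply(Filter(function(tr) tr$kind == "outer", traces),
                            function(tr) tr$length, 0L)
        t_sn <- 0.25 * mean(outer_len)
      }
      t_sn_used <- t_sn
      kept <- boundary_length_filter(traces, t_sn)
      kept <- lapply(kept, function(tr) {
        wb <- min(config$w_b, (tr$length - 2L) %/% 2L)
        if (wb >= 1L) smooth_boundary(tr, wb) else tr
      })
      filtered <- rebuild_blobs(kept, dim(filtered))
    }
  }

  if (any(filtered)) {
    s0 <- if (identical(config$s0, "auto"))
      estimate_area_threshold(filtered, config$pre_erosions) else config$s0
    seeds <- iterative_erosion_quantify(filtered, s0)
  } else {
    s0 <- NA_real_
    seeds <- structure(list(seeds = matrix(0L, nrow(img), ncol(img)),
                            iteration = integer(0), areas = integer(0),
                            n = 0L, n_iterations = 0L), class = "seed_set")
  }
  structure(list(
    centroids = seed_centroids(seeds),
    seeds = seeds,
    n_cells = seeds$n,
    thresholds = list(intensity = th_i, gradient = th_g),
    masks = list(s_i = s_i, s_g = s_g, s_u = s_u, filtered = filtered),
    s0 = s0, t_sn = t_sn_used,
    config = config
  ), class = "sdd_pipeline")
}

#' @export
print.sdd_pipeline <- function(x, ...) {
  cat("SDD segmentation pipeline result\n")
  if (!is.null(x$thresholds$intensity))
    cat("  intensity threshold:", x$thresholds$intensity$threshold, "\n")
  if (!is.null(x$thresholds$gradient))
    cat("  gradient threshold:", x$thresholds$gradient$threshold, "\n")
  cat("  area gate S0:", round(x$s0, 1), "\n")
  cat("  cells quantified:", x$n_cells, "\n")
  invisible(x)
}

#' Calibrate pipeline parameters
#'
#' Front end over the two calibration modes.  In `"f_measure"` mode the
#' `(N, W)` pair maximizing the mean mask F-measure over the supplied
#' image/truth pairs is written into the configuration (for the intensity or
#' the gradient threshold, per `target`).  In `"rational"` mode no truth is
#' needed: `N` is increased from the default until the SDD shows exactly
#' `class_count` dominant peaks.
#'
#' @param images list of numeric matrices (a single matrix is accepted).
#' @param truths list of logical ground-truth masks (`f_measure` mode only).
#' @param mode `"f_measure"` or `"rational"`.
#' @param config base configuration to update; default [pipeline_config()].
#' @param target `"intensity"` or `"gradient"`: which threshold the
#'   calibrated `(N, W)` applies to.
#' @param ... forwarded to [calibrate_grid()] or [calibrate_rational()].
#' @return the updated `"pipeline_config"`, with the `"calibration"` object
#'   attached as attribute `"calibration"`.
#' @export
run_calibration <- function(images, truths = NULL,
                            mode = c("f_measure", "rational"),
                            config = pipeline_config(),
                            target = c("intensity", "gradient"), ...) {
  mode <- match.arg(mode)
  target <- match.arg(target)
  if (is.matrix(images)) images <- list(images)
  if (mode == "f_measure") {
    if (is.null(truths)) stop2("f_measure calibration requires ground truth masks")
    if (is.matrix(truths)) truths <- list(truths)
    if (target == "gradient")
      images <- lapply(images, function(im)
        sobel_gradient(rescale_to_255(im)))
    cal <- calibrate_grid(images, truths,
                          class_count = if (target == "gradient") 2L
                                        else config$class_count, ...)
  } else {
    cal <- calibrate_rational(images[[1]],
                              class_count = if (target == "gradient") 2L
                                            else config$class_count, ...)
  }
  if (target == "intensity") {
    config$n_intensity <- cal$fit_points
    config$w_intensity <- cal$bandwidth
  } else {
    config$n_gradient <- cal$fit_points
    config$w_gradient <- cal$bandwidth
  }
  attr(config, "calibration") <- cal
  config
}
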