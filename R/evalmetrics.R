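#' Score a quantification result against ground truth
#'
#' Applies the per-cell counting metric: for every ground-truth cell region,
#' the number of identified cell centroids falling inside it is counted; a
#' region holding exactly one centroid is a true positive (TP), more than one
#' a false positive (FP), none a false negative (FN).  Each truth cell is
#' classified exactly once, so the TP, FP and FN counts sum to the number of
#' truth cells; rates are percentages of that number.  Centroids are mapped
#' to pixels by rounding, so a centroid on a region border counts for the
#' region owning that pixel.  Detections falling outside every truth region
#' do not enter the rates and are reported separately as `n_spurious`.
#'
#' @param result a `"seed_set"`, a centroid data frame with columns
#'   `row`/`col` (0-based), or a two-column matrix of centroids.
#' @param truth a ground-truth object from [make_cell_field()] or an integer
#'   label matrix with one positive label per true cell.
#' @return an object of class `"quant_score"`: list with `tp_rate`,
#'   `fp_rate`, `fn_rate` (percent), counts `n_truth`, `n_tp`, `n_fp`,
#'   `n_fn`, `n_spurious`, and `assignment` (data frame `truth_id`,
#'   `n_inside`, `status`).
#' @export
score_quantification <- function(result, truth) {
  labels <- if (is.list(truth) && !is.null(truth$labels)) truth$labels else truth
  if (!is.matrix(labels) || max(labels) < 1L)
    stop2("truth must contain at least one labelled cell region")
  cent <- if (inherits(result, "seed_set")) seed_centroids(result)
          else if (is.data.frame(result)) result
          else if (is.matrix(result)) data.frame(row = result[, 1],
                                                 col = result[, 2])
          else stop2("result must be a seed_set, data frame or matrix")
  n_truth <- max(labels)
  inside <- integer(n_truth)
  spurious <- 0L
  if (nrow(cent)) {
    r <- pmin(pmax(round_half_up(cent$row), 0), nrow(labels) - 1) + 1
    c <- pmin(pmax(round_half_up(cent$col), 0), ncol(labels) - 1) + 1
    hit <- labels[cbind(r, c)]
    spurious <- sum(hit == 0L)
    tab <- tabulate(hit[hit > 0L], nbins = n_truth)
    inside <- tab
  }
  status <- ifelse(inside == 1L, "TP", ifelse(inside > 1L, "FP", "FN"))
  n_tp <- sum(inside == 1L); n_fp <- sum(inside > 1L); n_fn <- sum(inside == 0L)
  structure(list(
    tp_rate = 100 * n_tp / n_truth,
    fp_rate = 100 * n_fp / n_truth,
    fn_rate = 100 * n_fn / n_truth,
    n_truth = n_truth, n_tp = n_tp, n_fp = n_fp, n_fn = n_fn,
    n_spurious = spurious,
    assignment = data.frame(truth_id = seq_len(n_truth), n_inside = inside,
                            status = status)
  ), class = "quant_score")
}

#' @export
print.quant_score <- function(x, ...) {
  cat(sprintf("Quantification score over %d truth cells:\n", x$n_truth))
  cat(sprintf("  TP %.1f%%  FP %.1f%%  FN %.1f%%  (%d spurious detections)\n",
              x$tp_rate, x$fp_rate, x$fn_rate, x$n_spurious))
  invisible(x)
}
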