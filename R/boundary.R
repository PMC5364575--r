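#' Trace blob and hole boundaries
#'
#' Extracts the closed boundary pixel sequence of every 8-connected
#' foreground component (outer contours, clockwise) and of every 4-connected
#' background hole enclosed by a component (hole contours, counterclockwise),
#' using Moore-neighbor tracing with Jacob's stopping criterion.  The trace
#' starts at a component's topmost-leftmost pixel; coordinates are 0-based
#' `(row, col)` at pixel centers.
#'
#' @param mask logical matrix.
#' @return list of traces, each a list with elements `points` (n x 2 integer
#'   matrix, columns `row`, `col`), `kind` (`"outer"` or `"hole"`), `parent`
#'   (the component label the trace belongs to) and `length` (`N_j`, the
#'   number of trace points).  Empty mask gives an empty list.
#' @export
trace_boundaries <- function(mask) {
  assert_mask(mask)
  labels <- label_components(mask, 8L)
  n_comp <- max(labels)
  traces <- list()
  if (n_comp == 0L) return(traces)
  for (id in seq_len(n_comp)) {
    pix <- which(labels == id, arr.ind = TRUE)
    start <- pix[order(pix[, 1], pix[, 2]), , drop = FALSE][1, ]
    pts <- moore_trace(mask, start[1], start[2])
    traces[[length(traces) + 1L]] <- list(
      points = pts - 1L, kind = "outer", parent = id, length = nrow(pts))
  }
  # holes: 4-connected background components not touching the image border
  bg <- label_components(!mask, 4L)
  if (max(bg) > 0L) {
    border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    hole_ids <- setdiff(seq_len(max(bg)), border_ids)
    for (hid in hole_ids) {
      hm <- bg == hid
      pix <- which(hm, arr.ind = TRUE)
      start <- pix[order(pix[, 1], pix[, 2]), , drop = FALSE][1, ]
      # parent blob: the foreground pixel above the hole's topmost pixel
      parent <- labels[start[1] - 1L, start[2]]
      pts <- moore_trace(hm, start[1], start[2])
      pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]  # counterclockwise
      traces[[length(traces) + 1L]] <- list(
        points = pts - 1L, kind = "hole", parent = parent, length = nrow(pts))
    }
  }
  traces
}

# Moore-neighbor boundary tracing (clockwise), 1-based (row, col) input and
# output; `start` must be the component's topmost-leftmost pixel
moore_trace <- function(mask, start_r, start_c) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]
  # clockwise neighbor offsets: N NE E SE S SW W NW
  dr <- c(-1L, -1L, 0L, 1L, 1L,  1L,  0L, -1L)
  dc <- c( 0L,  1L, 1L, 1L, 0L, -1L, -1L, -1L)
  pts <- matrix(c(start_r, start_c), 1, 2)
  cur <- c(start_r, start_c)
  # entered as if from the W neighbor, which is background by the choice of
  # start (topmost-leftmost pixel); direction index 7 = W
  back_dir <- 7L
  state <- function(p, d) ((p[1] - 1) * w + (p[2] - 1)) * 8 + d
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign(as.character(state(cur, back_dir)), TRUE, envir = seen)
  repeat {
    found <- FALSE
    for (k in 1:8) {
      d <- (back_dir + k - 1L) %% 8L + 1L
      nr <- cur[1] + dr[d]; nc <- cur[2] + dc[d]
      if (fg(nr, nc)) {
        prev <- (d - 2L) %% 8L + 1L  # neighbor examined just before the hit
        nxt <- c(nr, nc)
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    # new backtrack: the background neighbor examined just before the move,
    # expressed as a direction from the new pixel
    bpos <- cur + c(dr[prev], dc[prev])
    delta <- bpos - nxt
    new_back <- which(dr == delta[1] & dc == delta[2])
    # the walk state (pixel, backtrack) determines all subsequent steps, so
    # the contour is closed once a state recurs (normally the initial state)
    key <- as.character(state(nxt, new_back))
    if (exists(key, envir = seen, inherits = FALSE)) break
    assign(key, TRUE, envir = seen)
    pts <- rbind(pts, nxt)
    cur <- nxt
    back_dir <- new_back
  }
  dimnames(pts) <- list(NULL, c("row", "col"))
  pts
}

#' Drop short boundary traces
#'
#' Keeps traces with more than `threshold` points.  A removed outer trace
#' deletes its blob (its hole traces are dropped with it); a removed hole
#' trace means the hole is filled when the blobs are rebuilt.
#'
#' @param traces list from [trace_boundaries()].
#' @param threshold shape-noise length threshold `T_sn >= 0`.
#' @return filtered list of traces.
#' @export
boundary_length_filter <- function(traces, threshold) {
  if (threshold < 0) stop2("threshold must be >= 0")
  kept <- Filter(function(tr) tr$length > threshold, traces)
  outer_ids <- vapply(Filter(function(tr) tr$kind == "outer", kept),
                      function(tr) tr$parent, 0)
  Filter(function(tr) tr$kind == "outer" || tr$parent %in% outer_ids, kept)
}

#' Smooth a boundary trace by periodic Fourier low-pass filtering
#'
#' The `row` and `col` coordinate sequences of a closed trace are treated as
#' periodic signals of period `N_j` and filtered by the same low-pass DFT
#' scheme used for histograms (coefficients `0..W_b` and their conjugate
#' mirror retained), then rounded back to the pixel grid.  The `k = 0`
#' coefficient is untouched, so the trace centroid is conserved up to
#' rounding.
#'
#' @param trace a single trace from [trace_boundaries()].
#' @param bandwidth `W_b >= 1`; the trace must satisfy
#'   `N_j >= 2 * bandwidth + 2`.
#' @return the trace with smoothed `points` (rounded) and an additional
#'   `raw` element holding the unrounded smoothed coordinates.
#' @export
smooth_boundary <- function(trace, bandwidth) {
  wb <- as.integer(bandwidth)
  n <- trace$length
  if (is.na(wb) || wb < 1L) stop2("bandwidth must be >= 1")
  if (n < 2L * wb + 2L)
    stop2("trace of length ", n, " too short for bandwidth ", wb)
  lowpass <- function(x) {
    f <- stats::fft(x)
    keep <- logical(n)
    keep[1:(wb + 1L)] <- TRUE
    keep[(n - wb + 1L):n] <- TRUE
    f[!keep] <- 0
    Re(stats::fft(f, inverse = TRUE)) / n
  }
  raw <- cbind(row = lowpass(trace$points[, 1]),
               col = lowpass(trace$points[, 2]))
  trace$raw <- raw
  pts <- round_half_up(raw)
  storage.mode(pts) <- "integer"
  trace$points <- pts
  trace$length <- nrow(raw)
  trace
}

#' Rebuild a binary mask from boundary traces
#'
#' Fills every outer trace by even-odd polygon rasterization (plus the trace
#' pixels themselves), then subtracts the filled hole traces.  With
#' unfiltered, unsmoothed traces this inverts [trace_boundaries()] exactly.
#'
#' @param traces list of traces.
#' @param shape integer vector `c(rows, cols)` of the output mask.
#' @return logical matrix.
#' @export
rebuild_blobs <- function(traces, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  holes <- matrix(FALSE, shape[1], shape[2])
  for (tr in traces) {
    f <- fill_polygon(tr$points, shape)
    if (tr$kind == "outer") out <- out | f else holes <- holes | f
  }
  out & !holes
}

# pixels covered by a closed polygon given as 0-based (row, col) vertices:
# even-odd interior at pixel centers plus the (rounded, clamped) vertices
fill_polygon <- function(pts, shape) {
  out <- matrix(FALSE, shape[1], shape[2])
  n <- nrow(pts)
  if (n == 0L) return(out)
  r <- as.numeric(pts[, 1]); c <- as.numeric(pts[, 2])
  r2 <- c(r[-1], r[1]); c2 <- c(c[-1], c[1])
  keep <- r != r2  # horizontal edges never cross a scanline
  for (y in max(0, floor(min(r))):min(shape[1] - 1, ceiling(max(r)))) {
    cross <- keep & ((r > y) != (r2 > y))
    if (!any(cross)) next
    xs <- sort(c[cross] + (y - r[cross]) * (c2[cross] - c[cross]) /
                 (r2[cross] - r[cross]))
    for (i in seq(1, length(xs) - 1, by = 2)) {
      lo <- floor(xs[i]) + 1; hi <- ceiling(xs[i + 1]) - 1
      lo <- max(lo, 0); hi <- min(hi, shape[2] - 1)
      if (lo <= hi) out[y + 1, (lo:hi) + 1] <- TRUE
    }
  }
  # the boundary pixels themselves
  rr <- pmin(pmax(round_half_up(r), 0), shape[1] - 1)
  cc <- pmin(pmax(round_half_up(c), 0), shape[2] - 1)
  out[cbind(rr + 1, cc + 1)] <- TRUE
  out
}

#' Boundary smoothing filter
#'
#' Full shape-noise filter: trace all blob and hole boundaries, drop traces
#' of length `<= t_sn` (deleting small blobs and filling small holes),
#' low-pass filter the surviving contours' coordinate sequences, and rebuild
#' the blob image from the filtered boundaries.
#'
#' @param mask logical matrix.
#' @param t_sn shape-noise length threshold; `NULL` (default) uses
#'   0.25 x the mean outer-trace length of the mask's blobs.
#' @param bandwidth contour bandwidth `W_b`; default 10.  For surviving
#'   traces too short for the full bandwidth it is clamped per trace to
#'   `floor((N_j - 2) / 2)`.
#' @return logical matrix, the filtered blob image.
#' @export
boundary_smoothing_filter <- function(mask, t_sn = NULL, bandwidth = 10L) {
  assert_mask(mask)
  traces <- trace_boundaries(mask)
  if (!length(traces)) return(mask)
  if (is.null(t_sn)) {
    outer_len <- vapply(Filter(function(tr) tr$kind == "outer", traces),
                        function(tr) tr$length, 0L)
    t_sn <- 0.25 * mean(outer_len)
  }
  traces <- boundary_length_filter(traces, t_sn)
  traces <- lapply(traces, function(tr) {
    wb <- min(as.integer(bandwidth), (tr$length - 2L) %/% 2L)
    if (wb >= 1L) smooth_boundary(tr, wb) else tr
  })
  rebuild_blobs(traces, dim(mask))
}
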