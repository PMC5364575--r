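test_that("boundary tracing enumerates outer and hole contours", {
  expect_length(trace_boundaries(matrix(FALSE, 5, 5)), 0)

  # 4x6 rectangle: Moore trace visits the 16 perimeter pixels once
  m <- matrix(FALSE, 10, 12); m[3:6, 4:9] <- TRUE
  tr <- trace_boundaries(m)
  expect_length(tr, 1)
  expect_equal(tr[[1]]$length, 2 * (6 - 1) + 2 * (4 - 1))
  expect_equal(tr[[1]]$kind, "outer")
  # 0-based coordinates on the component's contour
  expect_true(all(m[tr[[1]]$points + 1L]))

  # rectangle with an interior hole: one outer + one hole trace
  m[4:5, 6:7] <- FALSE
  tr <- trace_boundaries(m)
  expect_setequal(vapply(tr, `[[`, "", "kind"), c("outer", "hole"))
  hole <- tr[[which(vapply(tr, `[[`, "", "kind") == "hole")]]
  expect_equal(hole$parent, tr[[1]]$parent)

  # a single pixel traces to itself
  px <- matrix(FALSE, 3, 3); px[2, 2] <- TRUE
  expect_equal(trace_boundaries(px)[[1]]$length, 1)
})

test_that("short traces are dropped, with holes filled and blobs deleted", {
  lengths <- function(trs) vapply(trs, `[[`, 0, "length")
  fake <- function(len, kind, parent) list(points = matrix(0L, len, 2),
                                           kind = kind, parent = parent,
                                           length = len)
  trs <- list(fake(10, "outer", 1), fake(50, "outer", 2),
              fake(200, "outer", 3), fake(8, "hole", 3))
  expect_equal(sort(lengths(boundary_length_filter(trs, 30))), c(50, 200))
  expect_length(boundary_length_filter(trs, 0), 4)
  # hole traces of deleted blobs are dropped with their parent
  trs2 <- list(fake(10, "outer", 1), fake(40, "hole", 1))
  expect_length(boundary_length_filter(trs2, 30), 0)

  # a small hole below the threshold is filled on rebuild
  m <- matrix(FALSE, 20, 20); m[4:16, 4:16] <- TRUE; m[9:10, 9:10] <- FALSE
  tr <- boundary_length_filter(trace_boundaries(m), 10)
  rebuilt <- rebuild_blobs(tr, dim(m))
  expect_identical(rebuilt, fill_holes_oracle(m))
})

test_that("trace -> rebuild is the identity for hole-free masks", {
  set.seed(10)
  for (i in 1:15) {
    m <- fill_holes_oracle(random_blob_mask())
    expect_identical(rebuild_blobs(trace_boundaries(m), dim(m)), m)
  }
  # and for masks with holes, via the hole traces
  ann <- matrix(FALSE, 30, 30); ann[5:25, 5:25] <- TRUE
  ann[12:16, 12:16] <- FALSE
  expect_identical(rebuild_blobs(trace_boundaries(ann), dim(ann)), ann)
})

test_that("contour smoothing preserves full-band traces and centroids", {
  m <- matrix(FALSE, 60, 60); m[15:45, 20:50] <- TRUE
  tr <- trace_boundaries(m)[[1]]
  full <- smooth_boundary(tr, (tr$length - 2L) %/% 2L)
  expect_lt(max(abs(full$raw - tr$points)), 1e-8)

  low <- smooth_boundary(tr, 2)
  expect_equal(colMeans(low$raw), colMeans(tr$points), tolerance = 1e-9)
  expect_error(smooth_boundary(tr, tr$length), "too short")
})

test_that("low-pass smoothing keeps circles and rounds square corners", {
  # circle: coordinate spectrum concentrated in harmonic 1
  circ <- ellipse_fixture(20)
  tr <- trace_boundaries(circ)[[1]]
  sm <- smooth_boundary(tr, 2)
  center <- colMeans(tr$points)
  rad <- sqrt(rowSums((sm$raw - rep(center, each = nrow(sm$raw)))^2))
  expect_lt(max(abs(rad - 20)), 1.5)

  # square of side 30, W_b = 2: corners rounded, bounded deviation
  sq <- matrix(FALSE, 50, 50); sq[10:39, 10:39] <- TRUE
  trq <- trace_boundaries(sq)[[1]]
  smq <- smooth_boundary(trq, 2)
  rebuilt <- rebuild_blobs(list(smq), dim(sq))
  dev <- sum(xor(rebuilt, sq)) / sum(sq)
  expect_gt(sum(xor(rebuilt, sq)), 0)          # corners visibly changed
  # max pointwise deviation bounded by 15% of the side
  d <- abs(smq$raw - 24.5)                      # distance from square center
  expect_lt(max(pmax(d[, 1], d[, 2])) - 14.5, 0.15 * 30)
  expect_lt(dev, 0.2)
})

test_that("the full boundary filter deletes debris and fills small holes", {
  m <- matrix(FALSE, 64, 64)
  m[8:30, 8:30] <- TRUE; m[40:58, 35:55] <- TRUE   # two large blobs
  m[16:18, 16:18] <- FALSE                          # small hole
  m[50, 5:8] <- TRUE                                # debris
  out <- boundary_smoothing_filter(m, bandwidth = 20)
  expect_equal(max(label_components(out)), 2)       # debris gone
  bg <- label_components(!out, 4)
  border <- unique(c(bg[1, ], bg[64, ], bg[, 1], bg[, 64]))
  expect_length(setdiff(unique(as.vector(bg)), c(0L, border)), 0)  # hole filled
})
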