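test_that("components below the gate are harvested whole at iteration 1", {
  m <- matrix(FALSE, 32, 32); m[4:12, 4:12] <- TRUE; m[18:26, 18:26] <- TRUE
  q <- iterative_erosion_quantify(m, 100)
  expect_equal(q$n, 2)
  expect_identical(q$seeds > 0, m)            # untouched by erosion
  expect_equal(q$iteration, c(1L, 1L))
  expect_equal(q$areas, c(81L, 81L))
})

test_that("a dumbbell is split into one seed per lobe", {
  m <- matrix(FALSE, 40, 60)
  m[10:24, 5:19] <- TRUE; m[10:24, 35:49] <- TRUE; m[16:18, 20:34] <- TRUE
  q <- iterative_erosion_quantify(m, 150)
  expect_equal(q$n, 2)
  ct <- seed_centroids(q)
  expect_true(any(ct$col < 20) && any(ct$col > 34))
  expect_true(all(ct$row > 13 & ct$row < 20))
})

test_that("degenerate quantification inputs behave sanely", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(iterative_erosion_quantify(empty, 50)$n, 0)
  expect_equal(nrow(seed_centroids(iterative_erosion_quantify(empty, 50))), 0)
  expect_error(iterative_erosion_quantify(empty, 0), "positive")
})

test_that("seed sets partition correctly for separated convex blobs", {
  set.seed(12)
  m <- matrix(FALSE, 80, 80)
  centers <- rbind(c(15, 15), c(15, 60), c(55, 20), c(60, 60), c(40, 40))
  for (i in seq_len(nrow(centers))) {
    r <- sample(4:7, 1)
    d <- outer(seq_len(80) - centers[i, 1], seq_len(80) - centers[i, 2],
               function(a, b) sqrt(a^2 + b^2))
    m <- m | (d <= r)
  }
  n_comp <- max(label_components(m))
  q <- iterative_erosion_quantify(m, 400)     # every blob below the gate
  expect_equal(q$n, n_comp)
  expect_true(all((q$seeds > 0) <= m))        # seeds subset of input
  # seeds disjoint by construction of the label matrix
  expect_equal(sum(q$areas), sum(q$seeds > 0))
})

test_that("the area gate estimate matches brute-force erosion", {
  m <- matrix(FALSE, 20, 20); m[5:15, 5:15] <- TRUE   # 11x11 square
  e1 <- erode_oracle(m)
  expect_equal(estimate_area_threshold(m, 1), sum(e1))
  expect_equal(estimate_area_threshold(m, 0), 121)

  two <- matrix(FALSE, 40, 40)
  two[2:11, 2:11] <- TRUE                              # area 100
  d <- outer(seq_len(40) - 28, seq_len(40) - 28, function(a, b) sqrt(a^2 + b^2))
  two <- two | (d <= 9.75)                             # area ~300
  expect_equal(estimate_area_threshold(two, 0),
               mean(component_areas_oracle(two)))
  # empty after erosion: falls back to the uneroded mean
  thin <- matrix(FALSE, 20, 20); thin[10, 3:17] <- TRUE
  expect_equal(estimate_area_threshold(thin, 3), 15)
  expect_error(estimate_area_threshold(matrix(FALSE, 5, 5)), "empty")
})

test_that("centroids are pixel-coordinate means", {
  m <- matrix(0L, 10, 10); m[8, 4] <- 1L
  expect_equal(seed_centroids(m)[1, c("row", "col")],
               data.frame(row = 7, col = 3))

  rect <- matrix(0L, 10, 25); rect[3:7, 11:21] <- 1L
  expect_equal(unlist(seed_centroids(rect)[1, c("row", "col")]),
               c(row = 4, col = 15))

  ell <- matrix(0L, 8, 8)
  px <- rbind(c(2, 2), c(3, 2), c(4, 2), c(4, 3), c(4, 4))   # L-shape
  ell[px] <- 1L
  expect_equal(unlist(seed_centroids(ell)[1, c("row", "col")]),
               c(row = mean(px[, 1] - 1), col = mean(px[, 2] - 1)))
})
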