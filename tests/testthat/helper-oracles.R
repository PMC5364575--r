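# Brute-force reference implementations used as independent oracles.
# They follow the set definitions literally, with explicit loops, and are
# deliberately independent of the package's vectorized code paths.

diamond_offsets <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))

# erosion: keep z iff every translate of the element lies in the mask
erode_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    ok <- TRUE
    for (k in 1:5) {
      rr <- r + diamond_offsets[k, 1]; cc <- c + diamond_offsets[k, 2]
      if (rr < 1 || rr > h || cc < 1 || cc > w || !m[rr, cc]) { ok <- FALSE; break }
    }
    out[r, c] <- ok
  }
  out
}

# dilation: keep z iff the reflected element translated to z hits the mask
dilate_oracle <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    hit <- FALSE
    for (k in 1:5) {
      rr <- r + diamond_offsets[k, 1]; cc <- c + diamond_offsets[k, 2]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && m[rr, cc]) { hit <- TRUE; break }
    }
    out[r, c] <- hit
  }
  out
}

# exhaustive minimum-misclassification threshold for a two-Gaussian mixture,
# scanning every cut point on the discretized gray axis
oracle_mixture_threshold <- function(w1, mu1, s1, mu2, s2) {
  err <- vapply(0:255, function(t)
    w1 * (1 - pnorm(t + 0.5, mu1, s1)) + (1 - w1) * pnorm(t + 0.5, mu2, s2),
    0)
  which.min(err) - 1L
}

# sample a seeded two-Gaussian mixture image in the overlapping regime the
# histogram model assumes (modes 2.5-3.5 sigma apart)
random_mixture <- function() {
  s1 <- runif(1, 14, 20); s2 <- runif(1, 14, 20)
  mu1 <- runif(1, 80, 100)
  mu2 <- mu1 + runif(1, 2.5, 3.5) * mean(c(s1, s2))
  w1 <- runif(1, 0.4, 0.6)
  n <- 20000L
  v <- c(rnorm(round(n * w1), mu1, s1), rnorm(n - round(n * w1), mu2, s2))
  list(image = matrix(pmin(pmax(round(v), 0), 255), 100),
       w1 = w1, mu1 = mu1, s1 = s1, mu2 = mu2, s2 = s2)
}

# random binary mask with blob-like structure (random field then opening)
random_blob_mask <- function(h = 48, w = 48, p = 0.5, open = 1) {
  m <- matrix(runif(h * w) < p, h, w)
  if (open > 0) m <- noise_blob_filter(m, open)
  m
}

# component areas via the package labeller (positions only; used where the
# quantity under test is the mean, not the labelling)
component_areas_oracle <- function(m) {
  lab <- label_components(m, 8L)
  tabulate(lab[lab > 0], nbins = max(lab))
}

# rasterized disk of radius r, centered in a square grid with margin
ellipse_fixture <- function(r, margin = 6) {
  n <- 2 * r + 2 * margin + 1
  ctr <- r + margin + 1
  d <- outer(seq_len(n) - ctr, seq_len(n) - ctr,
             function(a, b) sqrt(a^2 + b^2))
  d <= r
}

# fill all holes of a mask (4-connected background regions not touching the
# border), independently of the package's tracing machinery
fill_holes_oracle <- function(m) {
  bg <- label_components(!m, 4L)
  if (max(bg) == 0L) return(m)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  m | matrix(!(bg %in% c(0L, border)), nrow(m))
}
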