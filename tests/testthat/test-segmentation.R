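# Otsu thresholding, pooled histograms, binarization and cleanup

# independent oracle: exhaustive scan of every candidate split, class means
# computed directly; ties broken toward the lower threshold
otsu_oracle <- function(h) {
  centers <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  best <- -Inf
  k_best <- NA_integer_
  for (k in seq_len(h$n_bins - 1L)) {
    c0 <- h$counts[seq_len(k)]
    c1 <- h$counts[seq(k + 1L, h$n_bins)]
    w0 <- sum(c0); w1 <- sum(c1)
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(c0 * centers[seq_len(k)]) / w0
    m1 <- sum(c1 * centers[seq(k + 1L, h$n_bins)]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best * (1 + 1e-12)) {
      best <- v
      k_best <- k
    }
  }
  h$bin_edges[k_best + 1L]
}

random_histogram <- function() {
  n_bins <- sample(c(32L, 64L, 256L), 1)
  lo <- runif(1, -1, 1)
  edges <- seq(lo, lo + runif(1, 0.5, 3), length.out = n_bins + 1)
  kind <- sample(3, 1)
  counts <- switch(kind,
    rpois(n_bins, 50),
    {  # bimodal mixture
      x <- c(rnorm(5000, edges[round(n_bins * 0.25)], diff(range(edges)) / 20),
             rnorm(3000, edges[round(n_bins * 0.75)], diff(range(edges)) / 15))
      tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                            all.inside = TRUE), n_bins)
    },
    {  # sparse spikes
      counts <- integer(n_bins)
      counts[sample(n_bins, 5)] <- sample(1000, 5)
      counts
    })
  structure(list(bin_edges = edges, counts = counts, n_bins = n_bins),
            class = "mu_histogram")
}

test_that("Otsu equals the exhaustive between-class-variance scan", {
  set.seed(101)
  for (i in 1:30) {
    h <- random_histogram()
    if (sum(h$counts > 0) < 2) next
    expect_identical(otsu_threshold(h), otsu_oracle(h))
  }
})

test_that("Otsu separates two impulse classes and rejects degenerate input", {
  counts <- integer(256)
  counts[c(10, 200)] <- 1000L
  edges <- seq(0, 1.28, length.out = 257)
  h <- structure(list(bin_edges = edges, counts = counts, n_bins = 256L),
                 class = "mu_histogram")
  thr <- otsu_threshold(h)
  centers <- (edges[-1] + edges[-257]) / 2
  expect_gt(thr, centers[10])
  expect_lt(thr, centers[200])

  counts1 <- integer(256)
  counts1[40] <- 100L
  h1 <- structure(list(bin_edges = edges, counts = counts1, n_bins = 256L),
                  class = "mu_histogram")
  expect_error(otsu_threshold(h1), "degenerate")
  expect_error(attenuation_histogram(rep(0.5, 10)), "degenerate")
})

test_that("pooled histogram equals the histogram of concatenated voxels", {
  set.seed(7)
  vols <- lapply(1:3, function(i)
    ct_volume(array(runif(6^3, 0, 1 + i / 10), c(6, 6, 6)), 0.009))
  pooled <- pooled_histogram(vols, n_bins = 64)
  all_values <- unlist(lapply(vols, function(v) as.vector(v$grid)))
  ref <- attenuation_histogram(all_values, n_bins = 64,
                               range = range(all_values))
  expect_identical(pooled$counts, ref$counts)
  expect_equal(pooled$bin_edges, ref$bin_edges)
  expect_identical(common_threshold(vols, n_bins = 64), otsu_threshold(ref))
})

test_that("a series of identical scans has the single-scan threshold", {
  set.seed(8)
  v <- ct_volume(array(c(runif(500, 0, 0.2), runif(500, 1, 1.3)), c(10, 10, 10)),
                 0.009)
  expect_identical(common_threshold(list(v, v, v)), otsu_threshold(v))
  expect_error(common_threshold(list()), "non-empty")
  v2 <- v
  v2$voxel_size_mm <- 0.01
  expect_error(pooled_histogram(list(v, v2)), "metadata")
})

test_that("thresholding is monotone and inclusive (>= threshold)", {
  set.seed(9)
  v <- ct_volume(array(runif(8^3), c(8, 8, 8)), 1)
  m1 <- binarize_and_clean(v, 0.3, min_component_vox = 1L)$mask
  m2 <- binarize_and_clean(v, 0.6, min_component_vox = 1L)$mask
  expect_true(all(m1[m2]))            # raising the threshold never adds voxels
  expect_lte(sum(m2), sum(m1))
  v$grid[1, 1, 1] <- 0.3
  expect_true(binarize_and_clean(v, 0.3, min_component_vox = 1L)$mask[1, 1, 1])
})

test_that("component cleanup removes exactly the sub-threshold speckles", {
  # independent component census by brute-force BFS in R (6 & diagonal moves)
  bfs_sizes <- function(mask) {
    d <- dim(mask)
    seen <- array(FALSE, d)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    sizes <- integer(0)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (!mask[i, j, k] || seen[i, j, k]) next
      queue <- matrix(c(i, j, k), ncol = 3)
      seen[i, j, k] <- TRUE
      n <- 0L
      while (nrow(queue) > 0) {
        p <- queue[1, , drop = TRUE]
        queue <- queue[-1, , drop = FALSE]
        n <- n + 1L
        nb <- sweep(offs, 2, p, "+")
        ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
        for (r in which(ok)) {
          q <- nb[r, ]
          if (mask[q[1], q[2], q[3]] && !seen[q[1], q[2], q[3]]) {
            seen[q[1], q[2], q[3]] <- TRUE
            queue <- rbind(queue, q)
          }
        }
      }
      sizes <- c(sizes, n)
    }
    sizes
  }

  set.seed(12)
  g <- array(0, c(20, 20, 20))
  g[8:12, 8:12, 8:12] <- 1                  # 125-voxel block
  g[sample(which(g == 0), 40)] <- 1         # isolated salt noise
  v <- ct_volume(g, 0.009)
  before <- binarize_and_clean(v, 0.5, min_component_vox = 1L)$mask
  after <- binarize_and_clean(v, 0.5, min_component_vox = 27L)$mask
  expect_lte(sum(after), sum(before))
  expect_true(all(bfs_sizes(after) >= 27))
  # every removed voxel belonged to a component smaller than 27
  removed <- before & !after
  if (any(removed)) expect_true(all(bfs_sizes(removed) < 27))
  # the block survives
  expect_true(all(after[8:12, 8:12, 8:12]))
})

test_that("out-of-range thresholds warn and produce trivial masks", {
  v <- ct_volume(array(runif(5^3, 0.2, 0.8), c(5, 5, 5)), 1)
  expect_warning(m <- binarize_and_clean(v, 0.1, min_component_vox = 1L),
                 "all-full")
  expect_true(all(m$mask))
  expect_warning(m2 <- binarize_and_clean(v, 0.9, min_component_vox = 1L),
                 "all-empty")
  expect_false(any(m2$mask))
})

test_that("a noiseless phantom binarizes to its ground-truth bone labels", {
  sp <- small_phantom_spec(seed = 6)
  ph <- generate_bone_phantom(sp)
  thr <- otsu_threshold(ph$volume)
  expect_gt(thr, sp$mu_marrow)
  expect_lt(thr, sp$mu_trabecular)
  mask <- binarize_and_clean(ph$volume, thr)$mask
  truth_bone <- ph$truth$label_map >= 2L
  expect_identical(as.vector(mask), as.vector(truth_bone))
})
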