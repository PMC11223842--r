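# construct points whose 2x2 occupancy matrix (rows = y bin, cols = x bin)
# matches `counts`, for hand-checkable suppression cases
points_for_counts <- function(counts) {
  xs <- c(0.25, 0.75); ys <- c(0.25, 0.75)
  x <- y <- numeric(0)
  for (iy in 1:2) for (ix in 1:2) {
    k <- counts[iy, ix]
    x <- c(x, rep(xs[ix], k) + seq_len(k) * 1e-3)
    y <- c(y, rep(ys[iy], k) + seq_len(k) * 1e-3)
  }
  # anchor the corners so bin edges span exactly [0, 1] x [0, 1]
  calibration_points(c(0, 1, x), c(0, 1, y))
}

test_that("grid_count bins with right-closed top edge and conserves counts", {
  pts <- calibration_points(c(0, 1, 10), c(0, 1, 10))
  gs <- grid_count(pts, grid_spec(pts, 2, 2))
  expect_equal(sum(gs$counts), 3L)
  expect_equal(gs$counts[1, 1], 2L)  # (0,0) and (1,1) share the low/low cell
  expect_equal(gs$counts[2, 2], 1L)  # the maximum lands inside the top cell
  expect_equal(gs$counts[1, 2], 0L)
  expect_equal(gs$counts[2, 1], 0L)
})

test_that("grid_count conserves the total on random data", {
  set.seed(11)
  for (n in c(1L, 17L, 500L)) {
    pts <- calibration_points(runif(n + 1, 0, 50), runif(n + 1, 0, 9))
    gs <- grid_count(pts, grid_spec(pts, 13, 7))
    expect_equal(sum(gs$counts), n + 1L)
  }
})

test_that("grid_spec rejects degenerate ranges and tiny grids", {
  pts <- calibration_points(c(1, 1, 1), c(1, 2, 3))
  expect_error(grid_spec(pts), "degenerate range")
  pts2 <- calibration_points(c(1, 2, 3), c(5, 5, 5))
  expect_error(grid_spec(pts2), "degenerate range")
  pts3 <- calibration_points(c(1, 2), c(1, 2))
  expect_error(grid_spec(pts3, 1), ">= 2")
})

test_that("nonmax_suppress retains row and column maxima", {
  # counts (rows y, cols x): [[5,1],[2,7]] -> retained diagonal cells
  p1 <- points_for_counts(matrix(c(5, 2, 1, 7), nrow = 2))
  gs <- nonmax_suppress(grid_count(p1, grid_spec(p1, 2, 2)))
  got <- gs$retained[order(gs$retained$ix, gs$retained$iy), c("ix", "iy")]
  expect_equal(unname(as.matrix(got)), rbind(c(1L, 1L), c(2L, 2L)))

  # anti-diagonal maxima: [[1,9],[9,1]] -> cells (2,1) and (1,2)
  p2 <- points_for_counts(matrix(c(1, 9, 9, 1), nrow = 2))
  gs2 <- nonmax_suppress(grid_count(p2, grid_spec(p2, 2, 2)))
  got2 <- gs2$retained[order(gs2$retained$ix, gs2$retained$iy), c("ix", "iy")]
  expect_equal(unname(as.matrix(got2)), rbind(c(1L, 2L), c(2L, 1L)))

  # all mass in one cell -> that cell only
  p3 <- calibration_points(c(0, 0.1, 0.2, 10), c(0, 0.1, 0.2, 10))
  gs3 <- nonmax_suppress(grid_count(p3, grid_spec(p3, 2, 2)))
  expect_true(nrow(gs3$retained) <= 2L)
  expect_true(all(gs3$retained$freq > 0))
})

test_that("retained set size never exceeds size_x + size_y", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(c(5, 50, 2000), 1)
    sx <- sample(2:40, 1); sy <- sample(2:40, 1)
    pts <- calibration_points(runif(n), runif(n)^2)
    gs <- nonmax_suppress(grid_count(pts, grid_spec(pts, sx, sy)))
    expect_lte(nrow(gs$retained), sx + sy)
    expect_true(all(gs$retained$freq >= 1L))
  }
})

test_that("retained cells are invariant under increasing affine rescaling", {
  set.seed(31)
  pts <- calibration_points(runif(300, 0, 60), rnorm(300, 50, 10))
  base <- nonmax_suppress(grid_count(pts, grid_spec(pts, 20, 20)))$retained
  for (ab in list(c(3.7, -12), c(0.01, 5))) {
    resc <- calibration_points(ab[1] * pts$library_rt + ab[2],
                               pts$measured_rt)
    got <- nonmax_suppress(grid_count(resc, grid_spec(resc, 20, 20)))$retained
    expect_equal(got[, c("ix", "iy", "freq")], base[, c("ix", "iy", "freq")])
  }
})

test_that("retained node coordinates are the member-point means", {
  pts <- calibration_points(c(0, 0.1, 0.2, 10), c(0, 0.2, 0.4, 10))
  gs <- nonmax_suppress(grid_count(pts, grid_spec(pts, 2, 2)))
  low <- gs$retained[gs$retained$ix == 1 & gs$retained$iy == 1, ]
  expect_equal(low$x, mean(c(0, 0.1, 0.2)))
  expect_equal(low$y, mean(c(0, 0.2, 0.4)))
})
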