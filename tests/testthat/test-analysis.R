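test_that("radius of gyration matches direct geometry", {
  expect_equal(radius_of_gyration(matrix(1, 4, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  # translation / rotation invariance
  x <- matrix(rnorm(30, sd = 2), ncol = 3)
  rg <- radius_of_gyration(x)
  expect_equal(radius_of_gyration(sweep(x, 2, c(5, -3, 1), `+`)), rg)
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  expect_equal(radius_of_gyration(x %*% rot), rg)
  expect_error(radius_of_gyration(x, integer(0)))

  # volume relation and relative volume
  expect_equal(locus_volume(1), 4 * pi / 3)
  expect_equal(locus_volume(rg), 4 / 3 * pi * rg^3)
  expect_equal(relative_volume(3, 3), 1)
  expect_error(relative_volume(1, 0), "positive")
})

test_that("distance maps are symmetric, zero-diagonal and associative", {
  set.seed(8)
  frames1 <- lapply(1:3, function(i) matrix(rnorm(45), ncol = 3))
  frames2 <- lapply(1:5, function(i) matrix(rnorm(45), ncol = 3))
  m1 <- distance_map(frames1)
  expect_equal(unclass(m1), unclass(t(m1)))
  expect_equal(diag(m1), rep(0, 15))
  expect_true(all(m1 >= 0))

  # straight chain, single frame: entries are |i - j| * b
  b <- 0.9
  straight <- list(cbind(b * (0:9), 0, 0))
  ms <- distance_map(straight)
  expect_equal(ms[1, 10], 9 * b)
  expect_equal(matrix(unclass(ms), 10, 10), abs(outer(0:9, 0:9, "-")) * b)

  # pooling equals the map of the concatenated trajectory
  pooled <- pool_distance_maps(m1, distance_map(frames2))
  together <- distance_map(c(frames1, frames2))
  expect_equal(unclass(pooled), unclass(together))
  expect_equal(attr(pooled, "frame_count"), 8)
})

test_that("PRE proximity curves detect valleys at the other PRE", {
  # synthetic frames: beads on a line except the two "PREs" are pinned
  # next to each other in 3D
  topo <- build_default(n = 20, pre_indices = c(8L, 14L),
                        methylated_range = c(6L, 16L))
  mk <- function(jit) {
    pos <- cbind(0.97 * (1:20), 0, 0)
    pos[14, ] <- pos[8, ] + c(0.1, 1.0, 0) # PRE 14 folded back onto PRE 8
    pos + jit
  }
  set.seed(3)
  frames <- lapply(1:4, function(i) mk(matrix(rnorm(60, sd = 0.01), 20)))
  pc <- pre_proximity_curves(frames, topo)
  expect_equal(dim(pc$curves), c(2L, 20L))
  expect_equal(unname(pc$curves[1, 8]), 0, tolerance = 0.05)
  expect_true(pc$valleys[1, 2]) # curve of PRE 8 dips at bead 14
  expect_true(pc$valleys[2, 1])
  expect_lt(pc$curves[1, 14], pc$curves[1, 13])
})

test_that("chain statistics recover constructed geometry", {
  # rigid rod: exact bond length, enormous persistence length
  topo <- build_default(n = 30, pre_indices = integer(0),
                        methylated_range = c(10L, 20L))
  rod <- list(cbind(0.97 * (1:30), 0, 0))
  cs <- chain_stats(rod, topo)
  expect_equal(cs$bond_mean, 0.97)
  expect_equal(cs$cos_theta_mean, 1)
  expect_true(is.na(cs$persistence_length) ||
              cs$persistence_length > 1e3)
  expect_equal(cs$n_bonds, 29L)
})

test_that("summary statistics follow their stated constructions", {
  x <- c(1, 2, 3, 4, 100)
  ci <- summarize_ci(x[1:4])
  expect_equal(ci$mean, 2.5)
  expect_equal(ci$ci_hi - ci$mean, qt(0.975, 3) * sd(x[1:4]) / 2)
  expect_error(summarize_ci(1), "at least 2")

  bs <- boxplot_stats(x)
  expect_equal(bs$median, 3)
  expect_equal(bs$outliers, 100) # beyond 1.5 IQR of the quartiles
  expect_equal(bs$whisker_hi, 4)
  expect_equal(bs$whisker_lo, 1)

  # degenerate constant input
  cc <- summarize_ci(rep(2, 5))
  expect_equal(cc$ci_lo, 2)
  expect_equal(cc$ci_hi, 2)
  bc <- boxplot_stats(rep(2, 5))
  expect_equal(bc$whisker_lo, 2)
  expect_equal(bc$whisker_hi, 2)

  # t-interval coverage on repeated normal samples
  set.seed(99)
  cover <- mean(vapply(1:2000, function(i) {
    ci <- summarize_ci(rnorm(8, mean = 1))
    ci$ci_lo <= 1 && 1 <= ci$ci_hi
  }, logical(1)))
  expect_equal(cover, 0.95, tolerance = 0.02)
})
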