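test_that("random placement yields a valid connected chain", {
  topo <- chain60_topo()
  st <- random_placement(topo, box_large = 52, seed = 4)
  bl <- sqrt(rowSums((st$positions[topo$bonds[, 1], ] -
                      st$positions[topo$bonds[, 2], ])^2))
  expect_true(all(bl < ff_default$fene_r0))
  expect_equal(bl, rep(0.97, 59), tolerance = 1e-9)
  expect_equal(nrow(topo$bonds), 59L)
  expect_equal(nrow(topo$angles), 58L)
  # seeded reproducibility
  st2 <- random_placement(topo, box_large = 52, seed = 4)
  expect_identical(st$positions, st2$positions)
})

test_that("soft push-off separates overlapping beads", {
  fx <- make_fixture("dimer-overlap")
  st <- push_off(fx$state, fx$topo, ff_default, dp_default,
                 ramp_steps = 800, seed = 5)
  d <- sqrt(sum((st$positions[1, ] - st$positions[2, ])^2))
  expect_gt(d, 0.5) # separated from the constructed overlap

  # a full random-walk chain ends overlap-free (non-bonded pairs)
  topo <- chain60_topo()
  st0 <- random_placement(topo, box_large = 52, seed = 6)
  st1 <- push_off(st0, topo, ff_default, dp_default, seed = 7)
  dmin <- polyfold:::cpp_min_pair_dist(st1$positions, topo$bonds - 1L,
                                       st1$box_side, TRUE)
  expect_gte(dmin, 0.95)
  # an already valid state passes through without error
  st2 <- push_off(st1, topo, ff_default, dp_default, ramp_steps = 200,
                  seed = 8)
  expect_s3_class(st2, "system_state")
})

test_that("compression reaches the target density", {
  topo <- chain60_topo()
  st <- random_placement(topo, box_large = 52, seed = 9)
  st <- push_off(st, topo, ff_default, dp_default, seed = 10)
  stc <- compress(st, topo, ff_default, dp_default, target_side = 13,
                  steps = 500, seed = 11)
  expect_equal(stc$box_side, 13, tolerance = 1e-9)
  # bonds survive the shrink
  bl <- sqrt(rowSums((stc$positions[topo$bonds[, 1], ] -
                      stc$positions[topo$bonds[, 2], ])^2))
  expect_true(all(bl < ff_default$fene_r0))
  # no-op when already at the target
  expect_identical(compress(stc, topo, ff_default, dp_default,
                            target_side = 13), stc)
  expect_error(compress(stc, topo, ff_default, dp_default,
                        target_side = 20), "exceeds")
})

test_that("volume fractions match the density calibration", {
  expect_equal(volume_fraction(360, 24), 360 / 24^3)
  expect_equal(volume_fraction(360, 24), 0.026, tolerance = 0.01)
  expect_equal(nuclear_filling_fraction(), 0.021, tolerance = 0.01)
  # chain60 box preserves the production density
  expect_equal(volume_fraction(60, (60 / 0.026)^(1 / 3)), 0.026,
               tolerance = 1e-9)
})

test_that("equilibrated chain reproduces bond length and stiffness", {
  topo <- chain60_topo()
  st <- equilibrated_chain60()
  out <- run_dynamics(st, topo, ff_noattr, dp_default, 1.2e5,
                      sample_stride = 300, seed = 21)
  cs <- chain_stats(out$frames, topo)
  expect_gt(cs$n_bonds, 2e4)
  expect_equal(cs$bond_mean, 0.97, tolerance = 0.01)
  # persistence length: measured ~2.7 sigma, theoretical upper bound
  # Ktheta * sigma / kBT = 3 sigma
  expect_gt(cs$persistence_length, 2.4)
  expect_lt(cs$persistence_length, 3.0)
})
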