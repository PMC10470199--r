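# Protocol-level behaviour on cheap runs; the folding experiments
# themselves are exercised in test-acceptance.R.

test_that("occupancy across cycles is Binomial(n_pre, pb)", {
  topo <- build_default()
  st <- system_state(cbind(0.97 * seq_len(360), 0, 0), box_side = 400,
                     seed = 1)
  # 1-step cycles: we only care about the occupancy bookkeeping
  k <- vapply(1:1000, function(i) {
    out <- mcmd_cycle(st, topo, 0.7, ff_noattr, dp_default, n_steps = 1,
                      sample_stride = 2, seed = 7000L + i)
    out$n_bound
  }, integer(1))
  obs <- tabulate(k + 1L, nbins = 5L)
  expected <- dbinom(0:4, 4, 0.7) * 1000
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 4))
})

test_that("cycle resets occupancy and propagates state", {
  topo <- chain60_topo()
  st <- equilibrated_chain60()
  out <- mcmd_cycle(st, topo, 1, ff_default, dp_default, n_steps = 200,
                    sample_stride = 100, seed = 12)
  expect_equal(out$n_bound, 2L)
  expect_length(out$frames, 2)
  expect_equal(out$state$step_count, st$step_count + 200L)
  # the returned topology flags are untouched on the caller side
  expect_false(any(topo$prc1_bound))
})

test_that("degenerate cycles reduce to plain dynamics", {
  topo <- chain60_topo()
  st <- equilibrated_chain60()
  # pb = 0: no PRE is ever bound, identical to attraction-free dynamics
  seeds <- polyfold:::child_seeds(42, 2)
  out0 <- mcmd_cycle(st, topo, 0, ff_default, dp_default, n_steps = 300,
                     seed = 42)
  ref <- run_dynamics(st, topo, ff_noattr, dp_default, 300,
                      seed = seeds[2])
  expect_identical(out0$state$positions, ref$state$positions)
  # eps = 0 with every PRE bound: the well is empty
  out1 <- mcmd_cycle(st, topo, 1, ff_noattr, dp_default, n_steps = 300,
                     seed = 42)
  expect_identical(out1$state$positions, ref$state$positions)
})

test_that("experiment plan validates its grids", {
  topo <- chain60_topo()
  expect_error(experiment_plan(topo = topo, pb_values = c(0, 1.2)))
  expect_error(experiment_plan(topo = topo, replicates = 1))
  plan <- experiment_plan(topo = topo, replicates = 4, cycle_steps = 1000)
  expect_equal(plan$box_side, 13)
  expect_s3_class(plan, "experiment_plan")
})

test_that("PRE pair vs background extracts matched separations", {
  topo <- build_default(n = 20, pre_indices = c(8L, 14L),
                        methylated_range = c(6L, 16L))
  # straight chain: PRE pair distance equals the background exactly
  straight <- list(cbind(0.97 * (1:20), 0, 0))
  res <- pre_pair_vs_background(straight, topo)
  expect_equal(res$separation, 6)
  expect_equal(res$difference, 0, tolerance = 1e-12)
  # fold the PREs together: difference turns negative
  folded <- straight[[1]]
  folded[14, ] <- folded[8, ] + c(0, 1, 0)
  res2 <- pre_pair_vs_background(list(folded), topo)
  expect_lt(res2$difference, 0)
  expect_error(pre_pair_vs_background(straight,
                                      build_default(n = 20,
                                                    pre_indices = 8L,
                                                    methylated_range =
                                                      c(6L, 16L))),
               "two PREs")
})

test_that("dilution and affinity-scan drivers produce coherent summaries", {
  # ultra-short cycles: exercises the full driver paths and the summary
  # contracts, not the folding physics (covered in test-acceptance.R)
  topo <- chain60_topo()
  plan <- experiment_plan(topo = topo, pb_values = 1,
                          eps_values = c(0, 5.1),
                          dilution_fractions = c(1, 0.5),
                          replicates = 2, cycles = 1, cycle_steps = 2000,
                          equil_steps = 5000, sample_stride = 500,
                          seed = 55)
  dil <- suppressWarnings(run_dilution(plan))
  expect_equal(nrow(dil$summary), 2)
  expect_true(all(dil$summary$q1 <= dil$summary$median))
  expect_true(all(dil$summary$median <= dil$summary$q3))
  expect_equal(nrow(dil$ratios), 4)
  expect_true(all(dil$ratios$ratio > 0))

  scan <- suppressWarnings(run_eps_scan(plan))
  expect_named(scan$maps, c("eps_0", "eps_5.1"))
  m <- unclass(scan$maps[["eps_0"]])
  expect_equal(dim(m), c(20L, 20L))
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(0, 20))
  expect_equal(attr(scan$maps[["eps_5.1"]], "frame_count"), 8)
})
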