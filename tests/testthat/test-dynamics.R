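test_that("time-unit mapping follows tau = sigma^2 / D", {
  expect_equal(tau_from_diffusion(10, 5), 20)
  expect_equal(tau_from_diffusion(20, 5), 4 * tau_from_diffusion(10, 5))
  # one default MD step in physical time
  dp <- dynamics_params()
  expect_equal(dp$dt * dp$tau_us, 0.24)
})

test_that("undamped velocity Verlet conserves energy", {
  topo <- chain60_topo()
  st <- equilibrated_chain60()
  dpn <- dynamics_params(gamma = 0, dt = 0.006)
  e <- function(s) total_energy(s, topo, ff_noattr) +
    sum(s$velocities^2) / 2
  e0 <- e(st)
  drift <- c()
  for (i in 1:10) {
    st <- run_dynamics(st, topo, ff_noattr, dpn, 1000,
                       thermostat = FALSE)$state
    drift <- c(drift, abs(e(st) - e0) / abs(e0))
  }
  expect_lt(max(drift), 1e-3)
})

test_that("thermostat satisfies equipartition at kBT", {
  topo <- chain60_topo()
  st <- equilibrated_chain60()
  ke <- numeric(300)
  for (i in seq_along(ke)) {
    st <- run_dynamics(st, topo, ff_noattr, dp_default, 50)$state
    ke[i] <- mean(rowSums(st$velocities^2)) / 2
  }
  expect_equal(mean(ke), 1.5, tolerance = 0.05)
  # velocity components are zero-mean with variance kBT/m
  v <- st$velocities
  expect_lt(abs(mean(v)), 0.15)
})

test_that("identical seeds give bitwise-identical trajectories", {
  topo <- chain60_topo()
  st <- equilibrated_chain60()
  a <- run_dynamics(st, topo, ff_default, dp_default, 500,
                    sample_stride = 100, seed = 77)
  b <- run_dynamics(st, topo, ff_default, dp_default, 500,
                    sample_stride = 100, seed = 77)
  expect_identical(a$state$positions, b$state$positions)
  expect_identical(a$state$velocities, b$state$velocities)
  expect_identical(a$frames, b$frames)
  c <- run_dynamics(st, topo, ff_default, dp_default, 500,
                    sample_stride = 100, seed = 78)
  expect_false(identical(a$state$positions, c$state$positions))
})

test_that("neighbour-list forces are identical to the all-pairs loop", {
  topo <- chain60_topo()
  topo <- assign_prc1(topo, 1, seed = 9)
  st <- equilibrated_chain60()
  expect_equal(total_forces(st, topo, ff_default),
               total_forces(st, topo, ff_default, brute = TRUE),
               tolerance = 1e-12)
  # and along a short trajectory
  a <- run_dynamics(st, topo, ff_default, dp_default, 300, seed = 5)
  b <- run_dynamics(st, topo, ff_default, dp_default, 300, seed = 5,
                    brute = TRUE)
  expect_equal(a$state$positions, b$state$positions, tolerance = 1e-10)
})

test_that("frame sampling and bookkeeping behave as documented", {
  topo <- chain60_topo()
  st <- equilibrated_chain60()
  out <- run_dynamics(st, topo, ff_noattr, dp_default, 10,
                      sample_stride = 1, seed = 3)
  expect_length(out$frames, 10)
  expect_equal(attr(out$frames[[1]], "step"), st$step_count + 1L)
  expect_equal(attr(out$frames[[10]], "step"), st$step_count + 10L)
  expect_equal(attr(out$frames[[5]], "time_us"),
               (st$step_count + 5) * dp_default$dt * dp_default$tau_us)
  # stride larger than the run yields no frames
  out2 <- run_dynamics(st, topo, ff_noattr, dp_default, 5,
                       sample_stride = 10, seed = 3)
  expect_length(out2$frames, 0)
  expect_equal(out2$state$step_count, st$step_count + 5L)
})

test_that("overextended FENE bonds abort with the offending bond", {
  dimer <- polyfold:::new_topology(c("UNMETH", "UNMETH"), integer(0),
                                   c(0L, -1L))
  st <- system_state(rbind(c(0, 0, 0), c(1.6, 0, 0)), box_side = 50,
                     seed = 1)
  expect_error(total_forces(st, dimer, ff_default), "overextended")
  expect_error(langevin_step(st, dimer, ff_default, dp_default),
               "1-2")
})
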