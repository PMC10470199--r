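test_that("potential energies match hand-evaluated reference values", {
  p <- ff_default

  # FENE: zero at rest, frozen reference at 0.97 sigma, divergence at R0
  expect_equal(fene_energy(0, p), 0)
  expect_equal(fene_energy(0.97, p), 18.27867, tolerance = 1e-6)
  expect_identical(fene_energy(1.5, p), Inf)
  expect_identical(fene_energy(2.0, p), Inf)

  # bending: 0 / Ktheta / 2 Ktheta at 0, pi/2, pi
  expect_equal(bend_energy(0, p), 0)
  expect_equal(bend_energy(pi / 2, p), 3)
  expect_equal(bend_energy(pi, p), 6)

  # WCA: zero at its shifted minimum and beyond, eps_ev at r = sigma
  expect_equal(wca_energy(2^(1 / 6), p), 0)
  expect_equal(wca_energy(1, p), p$ev_eps)
  expect_equal(wca_energy(2, p), 0)

  # binding: zero at the cutoff, well depth at the LJ minimum
  expect_equal(bind_energy(p$bind_cutoff, p), 0)
  expect_equal(bind_energy(2^(1 / 6), p) / p$bind_eps, -0.9836831,
               tolerance = 1e-6)

  # soft push-off: 2A at contact, zero at the cutoff
  expect_equal(soft_energy(0, A = 40), 80)
  expect_equal(soft_energy(2.5, A = 40), 0)
  expect_equal(soft_energy(1.3, A = 0), 0)
})

test_that("binding well depth reproduces both cutoff conventions", {
  expect_equal(well_depth(1, 2.0), -0.938, tolerance = 1e-3)
  expect_equal(well_depth(1, 2.5), -0.9837, tolerance = 1e-4)
  expect_equal(well_depth(0, 2.0), 0)
  # scales linearly in eps
  expect_equal(well_depth(5.1, 2.0), 5.1 * well_depth(1, 2.0))
  expect_error(well_depth(1, 1.0), "cutoff")
})

test_that("pair potentials are continuous at their cutoffs", {
  p <- ff_default
  d <- 1e-8
  expect_lt(abs(wca_energy(2^(1 / 6) - d, p)), 1e-6)
  expect_lt(abs(bind_energy(p$bind_cutoff - d, p)), 1e-6)
  expect_lt(abs(soft_energy(2.5 - d, A = 40)), 1e-6)
})

test_that("parameter invariants are enforced", {
  expect_error(forcefield_params(fene_r0 = 0.9))
  expect_error(forcefield_params(bind_cutoff = 1.0), "bind_cutoff")
  expect_error(forcefield_params(fene_k = -1))
  expect_silent(forcefield_params(soft_amp = 0))
})

test_that("analytic forces match the central-difference gradient", {
  topo <- chain60_topo()
  topo <- assign_prc1(topo, 1, seed = 5)
  st <- equilibrated_chain60()
  f <- total_forces(st, topo, ff_default)
  beads <- c(1L, 15L, 26L, 34L, 41L, 60L)
  g <- numerical_forces(st, topo, ff_default, beads = beads)
  scale <- pmax(1, abs(f[beads, ]))
  expect_lt(max(abs(f[beads, ] - g) / scale), 1e-6)
})

test_that("internal forces sum to zero and obey Newton's third law", {
  topo <- chain60_topo()
  topo <- assign_prc1(topo, 1, seed = 5)
  st <- equilibrated_chain60()
  f <- total_forces(st, topo, ff_default)
  expect_lt(max(abs(colSums(f))), 1e-9)

  # isolated bonded dimer: equal and opposite forces along the bond axis
  dimer <- polyfold:::new_topology(c("UNMETH", "UNMETH"), integer(0),
                                   c(0L, -1L))
  stp <- system_state(rbind(c(0, 0, 0), c(0.97, 0, 0)), box_side = 50,
                      seed = 1)
  fd <- total_forces(stp, dimer, ff_default)
  expect_equal(fd[1, ], -fd[2, ])
  expect_equal(fd[1, 2:3], c(0, 0))

  # single isolated bead feels nothing
  single <- polyfold:::new_topology("UNMETH", integer(0), c(0L, -1L))
  sts <- system_state(matrix(c(1, 2, 3), 1), box_side = 50, seed = 1)
  expect_equal(total_forces(sts, single, ff_default),
               matrix(0, 1, 3))
})

test_that("attraction acts only between bound PREs and methylated beads", {
  # PRE (bead 1) and METH (bead 3) sit inside the attraction range but
  # beyond the WCA cutoff: any force between them must come from binding
  pos <- rbind(c(0, 0, 0), c(0.97, 0, 0), c(1.94, 0, 0))
  st <- system_state(pos, box_side = 50, seed = 1)

  f_bound <- total_forces(st, triplet_topo(bound = TRUE), ff_default)
  f_free <- total_forces(st, triplet_topo(bound = FALSE), ff_default)
  # unbound PRE: no direct 1-3 interaction at this separation
  e_bound <- total_energy(st, triplet_topo(TRUE), ff_default)
  e_free <- total_energy(st, triplet_topo(FALSE), ff_default)
  expect_equal(e_bound - e_free, bind_energy(1.94, ff_default))
  expect_false(isTRUE(all.equal(f_bound[1, 1], f_free[1, 1])))

  # eps = 0 disables the attraction entirely
  e0 <- total_energy(st, triplet_topo(TRUE), ff_noattr)
  expect_equal(e0, total_energy(st, triplet_topo(FALSE), ff_noattr))
  expect_equal(bind_energy(c(1.1, 1.5, 2.2), ff_noattr), c(0, 0, 0))
})
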