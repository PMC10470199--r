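# Shared miniature systems and numerical oracles for the test suite.

ff_default <- forcefield_params()
ff_noattr <- forcefield_params(bind_eps = 0)
dp_default <- dynamics_params()

chain60_topo <- function() make_fixture("chain60")$topo

# small pre-equilibrated chain cached per session (attraction off)
equilibrated_chain60 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      topo <- chain60_topo()
      st <- random_placement(topo, box_large = 52, seed = 101)
      st <- push_off(st, topo, ff_default, dp_default, seed = 102)
      st <- compress(st, topo, ff_default, dp_default, target_side = 13,
                     seed = 103)
      st <- suppressWarnings(
        equilibrate(st, topo, ff_default, dp_default, steps = 5e4,
                    seed = 104)$state)
      cache <<- st
    }
    cache
  }
})

# central-difference gradient of the total energy, the independent oracle
# for the analytic forces
numerical_forces <- function(state, topo, ffp, h = 1e-6, beads = NULL) {
  if (is.null(beads)) beads <- seq_len(topo$n_beads)
  g <- matrix(NA_real_, length(beads), 3)
  for (bi in seq_along(beads)) {
    for (d in 1:3) {
      sp <- state
      sp$positions[beads[bi], d] <- sp$positions[beads[bi], d] + h
      sm <- state
      sm$positions[beads[bi], d] <- sm$positions[beads[bi], d] - h
      g[bi, d] <- -(total_energy(sp, topo, ffp) -
                    total_energy(sm, topo, ffp)) / (2 * h)
    }
  }
  g
}

# tiny three-bead topology with one bound PRE and one methylated bead,
# for force-decomposition checks
triplet_topo <- function(bound = TRUE) {
  topo <- polyfold:::new_topology(c("PRE", "UNMETH", "METH"), 1L, c(1L, 3L))
  topo$prc1_bound[1] <- bound
  topo
}
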