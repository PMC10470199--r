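#' Random-walk placement of the chain in a large box
#'
#' Places the polymer as a freely jointed random walk with bond length
#' 0.97 \eqn{\sigma} (the equilibrium FENE+WCA bond length) inside a box
#' much larger than the target volume, so that periodic images play no
#' role before compression. Overlaps are allowed here; [push_off()]
#' removes them.
#'
#' @param topo A `polymer_topology`.
#' @param box_large Initial box side in \eqn{\sigma}; default 4x the
#'   24 \eqn{\sigma} production box.
#' @param seed Optional integer seed.
#' @param dp A [dynamics_params()] (for the velocity draw).
#' @return A [system_state()] with `n` beads, `n - 1` bonds implied by
#'   the topology, and Maxwell-Boltzmann velocities.
#' @export
random_placement <- function(topo, box_large = 96, seed = NULL,
                             dp = dynamics_params()) {
  n <- topo$n_beads
  pos <- with_seed(seed, {
    steps <- matrix(rnorm(3 * (n - 1)), ncol = 3)
    steps <- 0.97 * steps / sqrt(rowSums(steps^2))
    apply(rbind(matrix(0, 1, 3), steps), 2, cumsum)
  })
  pos <- sweep(pos, 2, colMeans(pos)) # centre the walk in the box
  vseed <- if (is.null(seed)) NULL else seed + 1L
  system_state(pos, box_side = box_large, kBT = dp$kBT, mass = dp$mass,
               seed = vseed,
               rng_state = if (is.null(seed)) 1L else seed)
}

#' Remove overlaps with a ramped soft push-off
#'
#' Replaces the non-bonded potentials with the cosine soft potential
#' \eqn{A(1 + \cos(\pi r / r_c))}, ramping the amplitude linearly from 0
#' to `ffp$soft_amp` (default 40 \eqn{k_BT}) over `ramp_steps` steps.
#' Afterwards the soft potential is dropped and the WCA/binding terms
#' apply again. Errors if any non-bonded pair remains closer than
#' `min_sep`, which indicates the ramp was too short.
#'
#' @inheritParams langevin_step
#' @param ramp_steps Length of the ramp in MD steps.
#' @param min_sep Required minimum non-bonded pair distance in
#'   \eqn{\sigma} after the ramp.
#' @return The overlap-free `system_state`.
#' @export
push_off <- function(state, topo, ffp, dp, ramp_steps = 1000L,
                     seed = NULL, min_sep = 0.95) {
  out <- md_run_internal(state, topo, ffp, dp, ramp_steps, 0L, seed,
                         mode = 1L, softA = c(0, ffp$soft_amp))
  st <- out$state
  if (topo$n_beads > 1) {
    dmin <- cpp_min_pair_dist(st$positions, topo$bonds - 1L, st$box_side,
                              TRUE)
    if (is.finite(dmin) && dmin < min_sep)
      stop(sprintf(paste0("residual overlap after push-off (min non-bonded",
                          " distance %.3f sigma); increase ramp_steps"),
                   dmin))
  }
  st
}

#' Compress the box to the target density
#'
#' Shrinks the periodic box geometrically to `target_side` over `steps`
#' MD steps, remapping positions affinely at each step. At the default
#' production settings (360 beads in a 24 \eqn{\sigma} box) the bead
#' volume fraction by the one-bead-per-\eqn{\sigma^3} counting convention
#' is 360/24^3 = 0.026, close to the nucleosome filling fraction of the
#' fly nucleus (about 0.021, see [nuclear_filling_fraction()]).
#'
#' @inheritParams langevin_step
#' @param target_side Final box side in \eqn{\sigma}.
#' @param steps MD steps over which the volume is reduced.
#' @return The compressed `system_state`.
#' @export
compress <- function(state, topo, ffp, dp, target_side = 24, steps = 500L,
                     seed = NULL) {
  if (target_side > state$box_side * (1 + 1e-9))
    stop("target_side exceeds the current box")
  if (abs(target_side - state$box_side) < 1e-9 * state$box_side)
    return(state)
  st <- md_run_internal(state, topo, ffp, dp, steps, 0L, seed,
                        box_end = target_side)$state
  st$box_side <- target_side # absorb geometric-schedule round-off
  st
}

#' Bead volume fraction of a cubic box
#'
#' Counting convention: one bead occupies one \eqn{\sigma^3} cell, so the
#' fraction is `n / side^3`.
#'
#' @param n Number of beads.
#' @param side Box side in \eqn{\sigma}.
#' @return Dimensionless filling fraction.
#' @examples
#' volume_fraction(360, 24) # 0.026
#' @export
volume_fraction <- function(n, side) {
  stopifnot(n > 0, side > 0)
  n / side^3
}

#' Nucleosome filling fraction of a nucleus
#'
#' Partitions the nuclear volume into bead-sized (\eqn{\sigma^3}) cells
#' and divides the nucleosome count by the number of cells. With the
#' defaults (a 78 um^3 fly nucleus, 2.88e8 bp of DNA at 175 bp per
#' nucleosome, 10 nm beads) this gives about 0.021, the density the
#' simulation box is calibrated to.
#'
#' @param nucleus_um3 Nuclear volume in um^3.
#' @param genome_bp Total DNA length in base pairs.
#' @param bp_per_nucleosome Base pairs per nucleosome.
#' @param sigma_nm Bead diameter in nm.
#' @return Dimensionless filling fraction.
#' @export
nuclear_filling_fraction <- function(nucleus_um3 = 78, genome_bp = 2.88e8,
                                     bp_per_nucleosome = 175,
                                     sigma_nm = 10) {
  n_nucleosomes <- genome_bp / bp_per_nucleosome
  n_cells <- nucleus_um3 / (sigma_nm * 1e-3)^3
  n_nucleosomes / n_cells
}

#' Equilibrate the chain with the attraction switched off
#'
#' Runs thermostatted dynamics with `bind_eps = 0` (PRC1 occupancy, if
#' any, has no effect) until the chain relaxes. Returns the final state
#' together with the sampled locus radius-of-gyration series; a warning
#' is emitted when the first- and second-half Rg means differ by more
#' than twice the between-sample spread, indicating the run was too
#' short.
#'
#' @inheritParams langevin_step
#' @param steps Equilibration length in MD steps (the full-scale
#'   production setting is 2e6; desk-scale runs use fewer).
#' @param sample_stride Interval for the Rg diagnostic samples.
#' @return `list(state, rg = numeric series, bond_mean)`.
#' @export
equilibrate <- function(state, topo, ffp, dp, steps = 2e5,
                        sample_stride = max(1L, floor(steps / 100)),
                        seed = NULL) {
  ffp0 <- ffp
  ffp0$bind_eps <- 0
  out <- md_run_internal(state, topo, ffp0, dp, steps, sample_stride, seed)
  idx <- topo$methylated_range[1]:topo$methylated_range[2]
  rg <- vapply(out$frames, radius_of_gyration, numeric(1), indices = idx)
  if (length(rg) >= 20) {
    h <- length(rg) %/% 2
    a <- rg[seq_len(h)]
    b <- rg[(h + 1):length(rg)]
    # Rg samples are autocorrelated, so compare half-means against the
    # full between-sample spread rather than a naive standard error
    spread <- sd(rg)
    if (spread > 0 && abs(mean(a) - mean(b)) > 1.5 * spread)
      warning("locus Rg still drifting at the end of equilibration; ",
              "consider more steps")
  }
  bonds <- vapply(out$frames, function(f)
    mean(sqrt(rowSums((f[topo$bonds[, 1], , drop = FALSE] -
                       f[topo$bonds[, 2], , drop = FALSE])^2))), numeric(1))
  list(state = out$state, rg = rg,
       bond_mean = if (length(bonds)) mean(bonds) else NA_real_)
}

#' Full preparation pipeline
#'
#' Random-walk placement in a large box, soft push-off, compression to
#' the target density, then attraction-free equilibration.
#'
#' @inheritParams equilibrate
#' @param target_side Production box side in \eqn{\sigma}.
#' @param equil_steps Equilibration length in MD steps.
#' @param seed Integer seed; expanded into independent seeds for each
#'   stage.
#' @return The equilibrated `system_state`.
#' @export
prepare_system <- function(topo, ffp = forcefield_params(),
                           dp = dynamics_params(), target_side = 24,
                           equil_steps = 2e5, seed = 1L) {
  seeds <- child_seeds(seed, 4L)
  st <- random_placement(topo, box_large = 4 * target_side, seed = seeds[1],
                         dp = dp)
  st <- push_off(st, topo, ffp, dp, seed = seeds[2])
  st <- compress(st, topo, ffp, dp, target_side = target_side,
                 seed = seeds[3])
  equilibrate(st, topo, ffp, dp, steps = equil_steps,
              seed = seeds[4])$state
}
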