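#' Setup for the many-particle binding calibration
#'
#' One immobile binding site at the centre of a periodic box surrounded
#' by diffusing binder particles. The implied particle concentration is
#' `n_particles / (N_A (box_side sigma)^3)`; the full-scale reference
#' setup (450 particles, 52 sigma box, sigma = 10 nm) corresponds to
#' about 5 uM. Scaled-down boxes keep the concentration by shrinking the
#' box with the particle count.
#'
#' @param n_particles Number of diffusing binder particles.
#' @param box_side Box side in \eqn{\sigma}.
#' @param eps_grid Attraction strengths (\eqn{k_BT}) to scan.
#' @param frames Bound/unbound samples per replicate (default 500).
#' @param replicates Independent replicate simulations per \eqn{\epsilon}.
#' @param bound_radius Centre-to-centre distance (in \eqn{\sigma}) below
#'   which the site counts as bound; defaults to the attraction range
#'   2.5 \eqn{\sigma}, the only length scale the interaction defines.
#' @param stride MD steps between samples (decorrelation interval).
#' @param burnin_steps MD steps discarded before sampling.
#' @param sigma_nm Physical bead diameter for the concentration report.
#' @return A `calibration_setup` list; `concentration_molar` holds the
#'   implied binder concentration.
#' @export
calibration_setup <- function(n_particles = 450, box_side = 52,
                              eps_grid = seq(3, 5, by = 0.5),
                              frames = 500, replicates = 4,
                              bound_radius = 2.5, stride = 1e4,
                              burnin_steps = 2e4, sigma_nm = 10) {
  stopifnot(n_particles >= 1, box_side > 2 * bound_radius,
            length(eps_grid) >= 1, frames >= 1, replicates >= 1)
  if (frames * replicates < 100)
    warning("fewer than 100 total samples; crossing estimate will be noisy")
  conc <- n_particles /
    (6.02214076e23 * (box_side * sigma_nm * 1e-8)^3)
  structure(list(n_particles = as.integer(n_particles),
                 box_side = box_side, eps_grid = eps_grid,
                 frames = as.integer(frames),
                 replicates = as.integer(replicates),
                 bound_radius = bound_radius, stride = as.integer(stride),
                 burnin_steps = as.integer(burnin_steps),
                 concentration_molar = conc),
            class = "calibration_setup")
}

#' Box side matching a target molar concentration
#'
#' @param n_particles Particle count.
#' @param conc_molar Target concentration in molar.
#' @param sigma_nm Bead diameter in nm.
#' @return Box side in \eqn{\sigma}.
#' @export
box_side_for_concentration <- function(n_particles, conc_molar,
                                       sigma_nm = 10) {
  stopifnot(n_particles >= 1, conc_molar > 0)
  litres <- n_particles / (6.02214076e23 * conc_molar)
  (litres)^(1 / 3) / (sigma_nm * 1e-8)
}

# A "topology" of free particles: no bonds, no angles; bead 1 is the
# site (attraction flag a), the rest are binders (flag b / "METH" slot).
particle_gas_topology <- function(n_particles) {
  n <- n_particles + 1L
  structure(list(
    n_beads = n,
    types = c("PRE", rep("METH", n_particles)),
    prc1_bound = c(TRUE, rep(FALSE, n_particles)),
    pre_indices = 1L,
    methylated_range = c(2L, n),
    bonds = matrix(integer(), 0, 2),
    angles = matrix(integer(), 0, 3)
  ), class = "polymer_topology")
}

#' Bound-fraction estimation across an attraction grid
#'
#' For each \eqn{\epsilon} in `setup$eps_grid` and each replicate, the
#' binder particles are placed uniformly (overlaps removed with a short
#' soft push-off), run to a burn-in, then sampled every `stride` steps;
#' a sample counts as bound when at least one particle centre lies
#' within `bound_radius` of the immobile site (minimum image). No
#' occupancy cap is imposed, so several particles may crowd the site at
#' strong attraction. Binder-binder interactions are WCA-repulsive only.
#'
#' @param setup A [calibration_setup()].
#' @param ffp A [forcefield_params()]; `bind_eps` is overridden by the
#'   grid value.
#' @param dp A [dynamics_params()].
#' @param seed Integer seed expanded into per-(eps, replicate) streams.
#' @return A data frame with one row per (eps, replicate): bound
#'   fraction `pb`, binomial standard error `se`, and sample count.
#' @export
binding_simulation <- function(setup, ffp = forcefield_params(),
                               dp = dynamics_params(), seed = 1L) {
  grid <- expand.grid(replicate = seq_len(setup$replicates),
                      eps = setup$eps_grid)
  seeds <- child_seeds(seed, nrow(grid))
  n <- setup$n_particles
  topo <- particle_gas_topology(n)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    eps <- grid$eps[g]
    ff <- ffp
    ff$bind_eps <- eps
    sds <- child_seeds(seeds[g], 3L)
    pos <- with_seed(sds[1], matrix(runif(3 * n, 0, setup$box_side),
                                    ncol = 3))
    pos <- rbind(rep(setup$box_side / 2, 3), pos) # immobile site centred
    st <- system_state(pos, box_side = setup$box_side, kBT = dp$kBT,
                       mass = dp$mass, seed = sds[1], rng_state = sds[2])
    st$velocities[1, ] <- 0
    mobile <- c(FALSE, rep(TRUE, n))
    # soft push-off so initial uniform placement cannot blow up
    st <- md_run_internal(st, topo, ff, dp, 500L, 0L, sds[2], mode = 1L,
                          softA = c(0, ffp$soft_amp), mobile = mobile)$state
    st <- md_run_internal(st, topo, ff, dp, setup$burnin_steps, 0L,
                          sds[3], mobile = mobile)$state
    bound <- logical(setup$frames)
    for (k in seq_len(setup$frames)) {
      st <- md_run_internal(st, topo, ff, dp, setup$stride, 0L, NULL,
                            mobile = mobile)$state
      d <- cpp_dist_to_site(st$positions, 0L, st$box_side)
      bound[k] <- any(d <= setup$bound_radius)
    }
    pb <- mean(bound)
    rows[[g]] <- data.frame(eps = eps, replicate = grid$replicate[g],
                            pb = pb,
                            se = sqrt(pb * (1 - pb) / setup$frames),
                            n_frames = setup$frames)
  }
  out <- do.call(rbind, rows)
  attr(out, "concentration_molar") <- setup$concentration_molar
  out
}

#' Interpolated crossing of the bound-fraction curve
#'
#' Linear interpolation of pb(\eqn{\epsilon}) at `level` between the
#' first bracketing grid points; the calibration reads off the
#' \eqn{\epsilon} at which the site is bound half the time.
#'
#' @param eps_values Attraction grid (\eqn{k_BT}), increasing.
#' @param pb_values Bound fractions at the grid points.
#' @param level Crossing level (default 0.5).
#' @return \eqn{\epsilon^*} in \eqn{k_BT}.
#' @examples
#' find_crossing(c(3, 5), c(0.4, 0.6)) # 4
#' @export
find_crossing <- function(eps_values, pb_values, level = 0.5) {
  stopifnot(length(eps_values) == length(pb_values),
            length(eps_values) >= 1)
  o <- order(eps_values)
  eps_values <- eps_values[o]
  pb_values <- pb_values[o]
  hit <- which(pb_values == level)
  if (length(hit)) return(eps_values[hit[1]])
  above <- pb_values >= level
  k <- which(above[-1] != above[-length(above)])
  if (!length(k)) stop("level not crossed by the pb curve")
  k <- k[1]
  eps_values[k] + (level - pb_values[k]) *
    (eps_values[k + 1] - eps_values[k]) / (pb_values[k + 1] - pb_values[k])
}
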