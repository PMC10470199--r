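#' Langevin dynamics parameters
#'
#' Reduced-unit integration settings. The damping rate \eqn{\Gamma} couples
#' beads to the implicit solvent; the thermostat noise amplitude
#' \eqn{\sqrt{2 m \Gamma k_BT / \Delta t}} enforces fluctuation-dissipation
#' balance at temperature `kBT`. The physical time unit follows from the
#' bead diffusion constant, \eqn{\tau = \sigma^2 / D} (20 microseconds at
#' the defaults), so one step spans `dt * tau_physical` of real time.
#'
#' @param kBT Thermal energy (reduced; default 1).
#' @param mass Bead mass (reduced; default 1).
#' @param gamma Damping rate \eqn{\Gamma} in \eqn{\tau^{-1}} (default 0.5).
#' @param dt Integration step in \eqn{\tau} (default 0.012).
#' @param diffusion Physical bead diffusion constant in um^2/s (default 5).
#' @param sigma_nm Physical bead diameter in nm (default 10).
#' @param seed Default integer seed for the noise stream.
#' @return A `dynamics_params` list; `tau_us` holds the derived physical
#'   time unit in microseconds.
#' @export
dynamics_params <- function(kBT = 1, mass = 1, gamma = 0.5, dt = 0.012,
                            diffusion = 5, sigma_nm = 10, seed = 1L) {
  stopifnot(kBT > 0, mass > 0, gamma >= 0, dt > 0)
  structure(list(kBT = kBT, mass = mass, gamma = gamma, dt = dt,
                 diffusion = diffusion, sigma_nm = sigma_nm,
                 tau_us = tau_from_diffusion(sigma_nm, diffusion),
                 seed = as.integer(seed)),
            class = "dynamics_params")
}

#' Map the reduced time unit to physical time
#'
#' \eqn{\tau = \sigma^2 / D}: for a 10 nm bead diffusing at 5 um^2/s,
#' \eqn{\tau} = 20 microseconds, so the default 0.012 \eqn{\tau} step is
#' 0.24 microseconds of real time.
#'
#' @param sigma_nm Bead diameter in nm.
#' @param D Diffusion constant in um^2/s.
#' @return \eqn{\tau} in microseconds.
#' @examples
#' tau_from_diffusion(10, 5) # 20
#' @export
tau_from_diffusion <- function(sigma_nm, D) {
  stopifnot(sigma_nm > 0, D > 0)
  (sigma_nm * 1e-3)^2 / D * 1e6
}

#' Construct a dynamics state
#'
#' @param positions `n x 3` matrix of bead coordinates in \eqn{\sigma}
#'   (kept unwrapped; periodic images are applied only inside the force
#'   loop).
#' @param velocities `n x 3` matrix in \eqn{\sigma/\tau}; defaults to a
#'   Maxwell-Boltzmann draw at `kBT` when omitted.
#' @param box_side Periodic box side L in \eqn{\sigma}.
#' @param kBT,mass Used for the default velocity draw.
#' @param step_count Completed integration steps.
#' @param rng_state Integer seed that the next run will consume unless an
#'   explicit seed is given; advanced deterministically after every run.
#' @param seed Seed for the default velocity draw.
#' @return A `system_state` object.
#' @export
system_state <- function(positions, velocities = NULL, box_side,
                         kBT = 1, mass = 1, step_count = 0L,
                         rng_state = 1L, seed = NULL) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)), box_side > 0)
  if (is.null(velocities)) {
    velocities <- with_seed(seed, matrix(
      rnorm(length(positions), sd = sqrt(kBT / mass)), ncol = 3))
  }
  structure(list(positions = positions, velocities = as.matrix(velocities),
                 box_side = box_side, step_count = as.integer(step_count),
                 rng_state = as.integer(rng_state)),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> %d beads | box %.3g sigma | step %d\n",
              nrow(x$positions), x$box_side, x$step_count))
  invisible(x)
}

# shared worker behind run_dynamics()/langevin_step()/push_off()/compress()
md_run_internal <- function(state, topo, ffp, dp, n_steps, sample_stride,
                            seed, mode = 0L, softA = c(0, 0),
                            box_end = NULL, use_nlist = TRUE,
                            thermostat = TRUE, mobile = NULL) {
  if (is.null(seed)) seed <- state$rng_state
  if (is.null(box_end)) box_end <- state$box_side
  if (is.null(mobile)) mobile <- rep(TRUE, topo$n_beads)
  res <- cpp_md_run(state$positions, state$velocities, topo$bonds - 1L,
                    topo$angles - 1L, topo$prc1_bound, topo$types == "METH",
                    mobile, state$box_side, box_end, unclass(ffp),
                    dp$kBT, dp$mass, dp$gamma, dp$dt,
                    as.integer(n_steps), as.integer(sample_stride),
                    as.integer(mode), softA[1], softA[2], as.double(seed),
                    use_nlist, thermostat)
  new_state <- state
  new_state$positions <- res$positions
  new_state$velocities <- res$velocities
  new_state$box_side <- res$box_side
  new_state$step_count <- state$step_count + as.integer(n_steps)
  new_state$rng_state <- as.integer((seed * 69069 + 12345) %% 2147483647)
  frames <- res$frames
  if (length(frames)) {
    for (k in seq_along(frames)) {
      attr(frames[[k]], "step") <- state$step_count + res$frame_steps[k]
      attr(frames[[k]], "time_us") <-
        (state$step_count + res$frame_steps[k]) * dp$dt * dp$tau_us
      attr(frames[[k]], "box_side") <- res$box_side
    }
  }
  list(state = new_state, frames = frames)
}

#' Advance the system by one velocity-Verlet Langevin step
#'
#' One integration step with conservative forces, friction
#' \eqn{-m\Gamma v} and Gaussian noise balancing it at `kBT`. With
#' `thermostat = FALSE` and `gamma = 0` the integrator reduces to plain
#' (energy-conserving) velocity Verlet.
#'
#' @param state A [system_state()].
#' @param topo A `polymer_topology`.
#' @param ffp A [forcefield_params()].
#' @param dp A [dynamics_params()].
#' @param seed Integer seed for the noise; defaults to `state$rng_state`.
#' @param thermostat Apply friction and noise (default `TRUE`).
#' @return The advanced `system_state`.
#' @export
langevin_step <- function(state, topo, ffp, dp, seed = NULL,
                          thermostat = TRUE) {
  md_run_internal(state, topo, ffp, dp, 1L, 0L, seed,
                  thermostat = thermostat)$state
}

#' Run Langevin dynamics and sample frames
#'
#' Integrates `n_steps` steps, recording the bead coordinates every
#' `sample_stride` completed steps. Frames carry `step`, `time_us` and
#' `box_side` attributes. Trajectories are bitwise reproducible from
#' (`state`, `seed`).
#'
#' @inheritParams langevin_step
#' @param n_steps Number of integration steps (>= 1).
#' @param sample_stride Sampling interval in steps; a stride larger than
#'   `n_steps` yields an empty frame list.
#' @param brute Use the all-pairs force loop instead of the neighbour
#'   list (identical forces; for cross-checks).
#' @return `list(state = final system_state, frames = list of n x 3
#'   matrices)`.
#' @export
run_dynamics <- function(state, topo, ffp, dp, n_steps,
                         sample_stride = n_steps + 1L, seed = NULL,
                         thermostat = TRUE, brute = FALSE) {
  stopifnot(n_steps >= 1)
  md_run_internal(state, topo, ffp, dp, n_steps,
                  if (sample_stride > n_steps) 0L else sample_stride,
                  seed, use_nlist = !brute, thermostat = thermostat)
}
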