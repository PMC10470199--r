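#' Force-field parameters for the bead-spring chromatin model
#'
#' Collects every interaction constant of the model in reduced units
#' (lengths in bead diameters \eqn{\sigma}, energies in \eqn{k_BT}).
#'
#' @param fene_k FENE bond strength \eqn{K_s} (\eqn{k_BT}).
#' @param fene_r0 FENE maximum extension \eqn{R_0} (\eqn{\sigma}).
#' @param bend_k Bending constant \eqn{K_\theta} (\eqn{k_BT}); sets the
#'   persistence length \eqn{l_p \approx K_\theta \sigma / k_BT}.
#' @param ev_eps Excluded-volume (WCA) strength \eqn{\epsilon_{ev}}
#'   (\eqn{k_BT}).
#' @param bind_eps Attraction strength \eqn{\epsilon} between PRC1-bound
#'   PREs and methylated beads (\eqn{k_BT}); 0 disables the attraction.
#' @param bind_cutoff Attraction range \eqn{r_{int}} (\eqn{\sigma}).
#' @param soft_amp Endpoint amplitude \eqn{A} of the soft push-off ramp
#'   (\eqn{k_BT}).
#' @param soft_cutoff Soft-potential range \eqn{r_c} (\eqn{\sigma}).
#' @param sigma_nm Physical bead diameter in nanometres (metadata only;
#'   all computations use \eqn{\sigma = 1}).
#'
#' @return An object of class `ff_params` (a validated named list).
#' @examples
#' p <- forcefield_params()
#' fene_energy(0.97, p)
#' @export
forcefield_params <- function(fene_k = 30, fene_r0 = 1.5, bend_k = 3,
                              ev_eps = 1, bind_eps = 5.1, bind_cutoff = 2.5,
                              soft_amp = 40, soft_cutoff = 2.5,
                              sigma_nm = 10) {
  p <- list(fene_k = fene_k, fene_r0 = fene_r0, bend_k = bend_k,
            ev_eps = ev_eps, bind_eps = bind_eps, bind_cutoff = bind_cutoff,
            soft_amp = soft_amp, soft_cutoff = soft_cutoff,
            sigma_nm = sigma_nm)
  stopifnot(fene_k > 0, fene_r0 > 1, bend_k > 0, ev_eps > 0, bind_eps >= 0,
            soft_amp >= 0, soft_cutoff > 0, sigma_nm > 0)
  if (bind_cutoff <= 2^(1 / 6))
    stop("bind_cutoff must exceed the LJ minimum 2^(1/6) sigma")
  structure(p, class = "ff_params")
}

#' @export
print.ff_params <- function(x, ...) {
  cat("<ff_params> (reduced units: sigma = kBT = 1)\n")
  cat(sprintf("  FENE: Ks = %g, R0 = %g | bend: Ktheta = %g\n",
              x$fene_k, x$fene_r0, x$bend_k))
  cat(sprintf("  WCA: eps_ev = %g | binding: eps = %g, r_int = %g\n",
              x$ev_eps, x$bind_eps, x$bind_cutoff))
  cat(sprintf("  soft push-off: A = %g, r_c = %g | sigma = %g nm\n",
              x$soft_amp, x$soft_cutoff, x$sigma_nm))
  invisible(x)
}

# Plain Lennard-Jones, sigma = 1.
lj <- function(r, eps) 4 * eps * ((1 / r)^12 - (1 / r)^6)

#' Pairwise and bonded potential energies
#'
#' Scalar (vectorised over `r` / `theta`) evaluations of the individual
#' potentials of the model. Energies are in \eqn{k_BT}, distances in
#' \eqn{\sigma}.
#'
#' * `fene_energy()`: finitely extensible bond,
#'   \eqn{-\tfrac12 K_s R_0^2 \ln(1 - (r/R_0)^2)}, infinite at
#'   \eqn{r \ge R_0}.
#' * `bend_energy()`: \eqn{K_\theta (1 - \cos\theta)} with \eqn{\theta}
#'   the angle between successive bond vectors (0 = straight chain).
#' * `wca_energy()`: Lennard-Jones truncated at its minimum
#'   \eqn{2^{1/6}\sigma} and shifted up by \eqn{\epsilon_{ev}} (purely
#'   repulsive excluded volume).
#' * `bind_energy()`: Lennard-Jones truncated at \eqn{r_{int}} and shifted
#'   so the energy is zero at the cutoff (PRC1-bound PRE to methylated
#'   bead attraction).
#' * `soft_energy()`: cosine push-off \eqn{A(1 + \cos(\pi r / r_c))} used
#'   during overlap removal.
#'
#' @param r Centre-to-centre distance(s) in \eqn{\sigma}.
#' @param theta Angle(s) between successive bond vectors, radians.
#' @param p A [forcefield_params()] object.
#' @param A Soft-potential amplitude in \eqn{k_BT}.
#' @param rc Soft-potential range in \eqn{\sigma}.
#' @return Energy in \eqn{k_BT}; `fene_energy()` returns `Inf` at or
#'   beyond the maximum extension.
#' @examples
#' p <- forcefield_params()
#' fene_energy(0.97, p)
#' bind_energy(2^(1 / 6), p) # bottom of the attraction well
#' @export
fene_energy <- function(r, p) {
  stopifnot(all(r >= 0))
  ifelse(r >= p$fene_r0, Inf,
         -0.5 * p$fene_k * p$fene_r0^2 * log(1 - (r / p$fene_r0)^2))
}

#' @rdname fene_energy
#' @export
bend_energy <- function(theta, p) {
  stopifnot(all(theta >= 0), all(theta <= pi + 1e-12))
  p$bend_k * (1 - cos(theta))
}

#' @rdname fene_energy
#' @export
wca_energy <- function(r, p) {
  stopifnot(all(r > 0))
  ifelse(r <= 2^(1 / 6), lj(r, p$ev_eps) + p$ev_eps, 0)
}

#' @rdname fene_energy
#' @export
bind_energy <- function(r, p) {
  stopifnot(all(r > 0))
  ifelse(r <= p$bind_cutoff,
         lj(r, p$bind_eps) - lj(p$bind_cutoff, p$bind_eps), 0)
}

#' @rdname fene_energy
#' @export
soft_energy <- function(r, A, rc = 2.5) {
  stopifnot(all(r >= 0), A >= 0, rc > 0)
  ifelse(r < rc, A * (1 + cos(pi * r / rc)), 0)
}

#' Depth of the truncated-shifted Lennard-Jones binding well
#'
#' The energy needed to move a bound test particle from the bottom of the
#' attraction well (\eqn{r_{min} = 2^{1/6}\sigma}) past the interaction
#' cutoff: \eqn{E_b = V_{LJ}(r_{min}) - V_{LJ}(cutoff)}. With a 2.0
#' \eqn{\sigma} cutoff this evaluates to \eqn{-0.938\epsilon}; with the
#' dynamics default 2.5 \eqn{\sigma} it is \eqn{-0.9837\epsilon}. The
#' 0.938 coefficient is the one used throughout the dissociation-constant
#' calibration (see [eps_from_kd()]).
#'
#' @param eps Attraction strength \eqn{\epsilon} in \eqn{k_BT}.
#' @param cutoff Attraction cutoff in \eqn{\sigma}; must exceed
#'   \eqn{2^{1/6}}.
#' @return \eqn{E_b} in \eqn{k_BT} (non-positive).
#' @examples
#' well_depth(1, 2.0) # -0.938
#' well_depth(1, 2.5) # -0.9837
#' @export
well_depth <- function(eps, cutoff = 2.0) {
  stopifnot(eps >= 0)
  if (cutoff <= 2^(1 / 6)) stop("cutoff must exceed r_min = 2^(1/6) sigma")
  if (eps == 0) return(0)
  lj(2^(1 / 6), eps) - lj(cutoff, eps)
}

#' Total forces on every bead
#'
#' Sums FENE bond, bending, WCA excluded-volume and (PRC1-bound PRE x
#' methylated) attraction forces under the minimum-image convention.
#' Attracting pairs interact through the binding potential alone (its
#' Lennard-Jones core already provides the repulsion); every other pair is
#' WCA-repulsive, including directly bonded neighbours (Kremer-Grest
#' convention, which yields the ~0.97 sigma mean bond length).
#'
#' @param state A [system_state()] object.
#' @param topo A [polymer_topology][build_default] object.
#' @param p A [forcefield_params()] object.
#' @param brute Use the all-pairs reference loop instead of the Verlet
#'   neighbour list (identical forces; used for cross-checks).
#' @return An `n x 3` matrix of forces in \eqn{k_BT/\sigma}.
#' @export
total_forces <- function(state, topo, p, brute = FALSE) {
  stopifnot(nrow(state$positions) == topo$n_beads)
  cpp_forces(state$positions, topo$bonds - 1L, topo$angles - 1L,
             topo$prc1_bound, topo$types == "METH", state$box_side,
             unclass(p), 0L, 0, !brute)
}

#' Total potential energy of a configuration
#'
#' Companion of [total_forces()]; same interaction terms and conventions.
#'
#' @inheritParams total_forces
#' @param soft If `TRUE`, evaluate the soft push-off potential (amplitude
#'   `A`) in place of the non-bonded terms.
#' @param A Soft amplitude in \eqn{k_BT} when `soft = TRUE`.
#' @return Potential energy in \eqn{k_BT}.
#' @export
total_energy <- function(state, topo, p, soft = FALSE, A = 0) {
  cpp_energy(state$positions, topo$bonds - 1L, topo$angles - 1L,
             topo$prc1_bound, topo$types == "METH", state$box_side,
             unclass(p), if (soft) 1L else 0L, A)
}
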