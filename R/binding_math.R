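#' Equilibrium site-occupancy probability
#'
#' For a pseudo first-order binding reaction at binder concentration `c`
#' and dissociation constant `kd`, the probability that the site is
#' occupied is \eqn{p_b = c / (c + K_D)}. Applied both to PRC1 binding
#' PREs (giving `pb_pre`) and to PRC1 binding H3K27me3.
#'
#' @param c Free-binder concentration, molar.
#' @param kd Dissociation constant, molar.
#' @return Probability in \[0, 1\].
#' @examples
#' pb_bound(0.2e-6, 200e-9) # 0.5
#' @export
pb_bound <- function(c, kd) {
  stopifnot(all(c >= 0), all(kd >= 0))
  if (any(c == 0 & kd == 0)) stop("c and kd cannot both be zero")
  c / (c + kd)
}

#' Dissociation constant giving a target occupancy
#'
#' Inverts [pb_bound()]: \eqn{K_D = c (1 - p_b) / p_b}.
#'
#' @param pb Occupancy probability in (0, 1\].
#' @param c Binder concentration, molar.
#' @return \eqn{K_D} in molar.
#' @examples
#' kd_for_pb(0.5, 0.2e-6) # 2e-7 (200 nM)
#' @export
kd_for_pb <- function(pb, c) {
  stopifnot(all(pb > 0), all(pb <= 1), all(c >= 0))
  c * (1 - pb) / pb
}

#' Standard-state concentration of the reduced-unit box
#'
#' One particle per \eqn{\sigma^3} cell: \eqn{c_0 = 1 / (N_A \sigma^3)}.
#' For \eqn{\sigma} = 10 nm this is 1.66e-3 M (often quoted rounded as
#' 1.67 mM); it converts binding energies into dissociation constants in
#' [kd_from_eps()] / [eps_from_kd()].
#'
#' @param sigma_nm Bead diameter in nm.
#' @return Concentration in molar.
#' @examples
#' standard_state(10)
#' @export
standard_state <- function(sigma_nm = 10) {
  stopifnot(sigma_nm > 0)
  avogadro <- 6.02214076e23
  litres_per_cell <- (sigma_nm * 1e-8)^3 # (nm -> dm)^3 = litres
  1 / (avogadro * litres_per_cell)
}

#' Dissociation constant implied by a Lennard-Jones strength
#'
#' \eqn{K_D = c_0 e^{E_b / k_BT} \approx c_0 e^{-0.938 \epsilon}}, using
#' the binding well depth \eqn{E_b = -0.938\epsilon} of the truncated
#' Lennard-Jones attraction (see [well_depth()]; with the exact 2.5
#' \eqn{\sigma} cutoff the coefficient is 0.9837, selectable through
#' `well_coeff`).
#'
#' @param eps Attraction strength in \eqn{k_BT} (>= 0).
#' @param c0 Standard-state concentration, molar.
#' @param well_coeff Magnitude of the well-depth coefficient per unit
#'   \eqn{\epsilon}.
#' @return \eqn{K_D} in molar.
#' @export
kd_from_eps <- function(eps, c0 = standard_state(), well_coeff = 0.938) {
  stopifnot(all(eps >= 0), c0 > 0, well_coeff > 0)
  c0 * exp(-well_coeff * eps)
}

#' Lennard-Jones strength required for a target dissociation constant
#'
#' Inverts [kd_from_eps()]:
#' \eqn{\epsilon / k_BT = (1 / 0.938) \ln(c_0 / K_D)}. At
#' \eqn{K_D} = 5 uM and \eqn{c_0} = 1.67 mM this gives 6.20 \eqn{k_BT},
#' the theoretical half of the consensus calibration.
#'
#' @param kd Dissociation constant, molar; must not exceed `c0` (the
#'   mapping only covers attractive wells).
#' @inheritParams kd_from_eps
#' @return \eqn{\epsilon} in \eqn{k_BT}.
#' @examples
#' eps_from_kd(5e-6, c0 = 1.67e-3) # about 6.20
#' @export
eps_from_kd <- function(kd, c0 = standard_state(), well_coeff = 0.938) {
  stopifnot(all(kd > 0), c0 > 0)
  if (any(kd > c0))
    stop("kd > c0 would require a repulsive (negative) epsilon")
  log(c0 / kd) / well_coeff
}

#' Consensus attraction strength from the two calibrations
#'
#' Arithmetic mean of the simulation-derived estimate (crossing of the
#' bound-fraction curve at p_b = 0.5, about 3.94 \eqn{k_BT} at
#' \eqn{K_D} = 5 uM) and the closed-form estimate ([eps_from_kd()],
#' 6.20 \eqn{k_BT}); the mean, 5.07, is rounded to 5.1 \eqn{k_BT} as the
#' production attraction strength.
#'
#' @param eps_sim Simulation estimate in \eqn{k_BT}.
#' @param eps_theory Closed-form estimate in \eqn{k_BT}.
#' @return Consensus \eqn{\epsilon} in \eqn{k_BT}.
#' @examples
#' eps_consensus(3.94, 6.20) # 5.07
#' @export
eps_consensus <- function(eps_sim, eps_theory) {
  stopifnot(eps_sim >= 0, eps_theory >= 0)
  (eps_sim + eps_theory) / 2
}

#' Parse a concentration string with nM/uM/mM/M suffix
#'
#' @param x Character like `"200nM"`, `"0.2 uM"`, `"1.67mM"`, or a bare
#'   number taken as molar.
#' @return Concentration in molar.
#' @export
parse_concentration <- function(x) {
  if (is.numeric(x)) return(x)
  m <- regmatches(x, regexec(
    "^\\s*([0-9.eE+-]+)\\s*(nM|uM|µM|mM|M)?\\s*$", x))[[1]]
  if (length(m) < 2 || m[2] == "") stop("cannot parse concentration: ", x)
  val <- as.numeric(m[2])
  unit <- if (length(m) >= 3 && nzchar(m[3])) m[3] else "M"
  val * switch(unit, nM = 1e-9, uM = 1e-6, "µM" = 1e-6, mM = 1e-3,
               M = 1)
}

#' Tabulate the dissociation-constant / attraction-strength mapping
#'
#' @param eps Vector of attraction strengths in \eqn{k_BT}.
#' @inheritParams kd_from_eps
#' @return A data frame with columns `eps_kBT`, `Eb_kBT`, `kd_molar`.
#' @export
calibration_table <- function(eps = seq(0, 10, by = 0.5),
                              c0 = standard_state(), well_coeff = 0.938) {
  data.frame(eps_kBT = eps, Eb_kBT = -well_coeff * eps,
             kd_molar = kd_from_eps(eps, c0, well_coeff))
}
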