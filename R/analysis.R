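#' Radius of gyration of a bead selection
#'
#' Root-mean-square distance of the selected beads from their centroid,
#' computed on unwrapped coordinates. For the production layout the
#' selection defaults to the methylated locus (beads 120--240 of the
#' 360-mer) when called through [locus_geometry()].
#'
#' @param positions `n x 3` coordinate matrix in \eqn{\sigma}
#'   (unwrapped).
#' @param indices 1-based bead indices to include (default: all).
#' @return Rg in \eqn{\sigma}.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))) # 0.5
#' @export
radius_of_gyration <- function(positions, indices = NULL) {
  if (!is.null(indices)) {
    stopifnot(length(indices) >= 1)
    positions <- positions[indices, , drop = FALSE]
  }
  if (nrow(positions) == 0) stop("empty bead selection")
  centred <- sweep(positions, 2, colMeans(positions))
  sqrt(mean(rowSums(centred^2)))
}

#' Locus volume from the radius of gyration
#'
#' \eqn{V = \tfrac{4}{3}\pi R_g^3}, the sphere-equivalent volume used as
#' the folding readout.
#'
#' @param rg Radius of gyration in \eqn{\sigma} (>= 0).
#' @return Volume in \eqn{\sigma^3}.
#' @export
locus_volume <- function(rg) {
  stopifnot(all(rg >= 0))
  4 / 3 * pi * rg^3
}

#' @rdname locus_volume
#' @param v Volume in \eqn{\sigma^3}.
#' @param v_ref Reference volume in \eqn{\sigma^3} (> 0), typically the
#'   mean locus volume of the matching no-PRE layout.
#' @return `relative_volume()`: the dimensionless ratio `v / v_ref`.
#' @export
relative_volume <- function(v, v_ref) {
  if (any(v_ref <= 0)) stop("v_ref must be positive")
  v / v_ref
}

#' Locus geometry of one frame
#'
#' @param positions `n x 3` coordinate matrix.
#' @param topo A `polymer_topology`; the locus interval supplies the
#'   default selection.
#' @param indices Optional explicit bead selection.
#' @return A list with `rg` (\eqn{\sigma}), `volume` (\eqn{\sigma^3})
#'   and the indices used.
#' @export
locus_geometry <- function(positions, topo, indices = NULL) {
  if (is.null(indices))
    indices <- topo$methylated_range[1]:topo$methylated_range[2]
  rg <- radius_of_gyration(positions, indices)
  list(rg = rg, volume = locus_volume(rg), indices = indices)
}

#' Mean pairwise-distance map of a trajectory
#'
#' Elementwise mean over frames of the 3D distance between every bead
#' pair (unwrapped coordinates; the chain never spans the box at the
#' simulated density). Folded states show reduced in-locus distances and
#' PRE-PRE "off-diagonal spots".
#'
#' @param frames List of `n x 3` coordinate matrices.
#' @param indices Optional bead selection restricting the map.
#' @return A symmetric matrix (class `distance_map`) of mean distances
#'   in \eqn{\sigma}, zero diagonal, with a `frame_count` attribute.
#' @export
distance_map <- function(frames, indices = NULL) {
  stopifnot(length(frames) >= 1)
  acc <- NULL
  for (f in frames) {
    if (!is.null(indices)) f <- f[indices, , drop = FALSE]
    d <- as.matrix(stats::dist(f))
    acc <- if (is.null(acc)) d else acc + d
  }
  m <- acc / length(frames)
  dimnames(m) <- NULL
  attr(m, "frame_count") <- length(frames)
  class(m) <- c("distance_map", class(m))
  m
}

#' Pool distance maps weighted by frame counts
#'
#' Averaging is associative: the map of a concatenated trajectory equals
#' the frame-count-weighted mean of the per-part maps.
#'
#' @param ... `distance_map` objects of equal dimension.
#' @return The pooled `distance_map`.
#' @export
pool_distance_maps <- function(...) {
  maps <- list(...)
  w <- vapply(maps, attr, numeric(1), "frame_count")
  m <- Reduce(`+`, Map(function(x, wi) unclass(x) * wi, maps, w)) / sum(w)
  attr(m, "frame_count") <- sum(w)
  class(m) <- c("distance_map", class(m))
  m
}

#' Mean 3D distance from each PRE to every bead
#'
#' One curve per PRE: the trajectory-average distance between that PRE
#' and each bead index. Under folding conditions the curve dips ("forms
#' a valley") at the positions of the other PREs, the per-locus
#' signature of PRE clustering.
#'
#' @param frames List of coordinate matrices.
#' @param topo A `polymer_topology` with at least one PRE.
#' @return A list with `curves` (matrix, one row per PRE, one column per
#'   bead), `pre_indices`, and `valleys` (logical matrix flagging, for
#'   each curve, the other-PRE positions whose mean distance is below
#'   both flanking non-PRE beads).
#' @export
pre_proximity_curves <- function(frames, topo) {
  if (!length(topo$pre_indices)) stop("topology has no PREs")
  dm <- unclass(distance_map(frames))
  curves <- dm[topo$pre_indices, , drop = FALSE]
  rownames(curves) <- paste0("PRE_", topo$pre_indices)
  npre <- length(topo$pre_indices)
  valleys <- matrix(FALSE, npre, npre,
                    dimnames = list(rownames(curves),
                                    paste0("at_", topo$pre_indices)))
  for (i in seq_len(npre)) {
    for (j in seq_len(npre)) {
      if (i == j) next
      q <- topo$pre_indices[j]
      lo <- if (q > 1) curves[i, q - 1] else Inf
      hi <- if (q < topo$n_beads) curves[i, q + 1] else Inf
      valleys[i, j] <- curves[i, q] < lo && curves[i, q] < hi
    }
  }
  list(curves = curves, pre_indices = topo$pre_indices, valleys = valleys)
}

#' Bond-length and stiffness statistics of a trajectory
#'
#' Chain-and-time averages over equilibrated frames: mean bond length
#' and the persistence length estimated from the bond-direction
#' correlation of adjacent bonds,
#' \eqn{l_p = -\langle b\rangle / \ln\langle\cos\theta\rangle}.
#'
#' @param frames List of coordinate matrices.
#' @param topo A `polymer_topology`.
#' @return A list with `bond_mean`, `bond_se`, `cos_theta_mean`,
#'   `persistence_length` (all lengths in \eqn{\sigma}) and `n_bonds`
#'   (total bond samples).
#' @export
chain_stats <- function(frames, topo) {
  stopifnot(length(frames) >= 1)
  b1 <- topo$bonds[, 1]
  b2 <- topo$bonds[, 2]
  per_frame_b <- numeric(length(frames))
  per_frame_c <- numeric(length(frames))
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    bv <- f[b2, , drop = FALSE] - f[b1, , drop = FALSE]
    bl <- sqrt(rowSums(bv^2))
    u <- bv / bl
    nb <- nrow(u)
    per_frame_b[k] <- mean(bl)
    per_frame_c[k] <- mean(rowSums(u[-nb, , drop = FALSE] *
                                   u[-1, , drop = FALSE]))
  }
  bond_mean <- mean(per_frame_b)
  cosm <- mean(per_frame_c)
  list(bond_mean = bond_mean,
       bond_se = sd(per_frame_b) / sqrt(length(frames)),
       cos_theta_mean = cosm,
       persistence_length = if (cosm >= 1) Inf else
         if (cosm > 0) -bond_mean / log(cosm) else NA_real_,
       n_bonds = length(frames) * nrow(topo$bonds))
}

#' Mean with a Student-t 95 percent confidence interval
#'
#' @param values Numeric, at least 2 observations (replicate means).
#' @param level Confidence level (default 0.95).
#' @return A list with `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
summarize_ci <- function(values, level = 0.95) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values for an interval")
  m <- mean(values)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(values) / sqrt(n)
  list(mean = m, ci_lo = m - half, ci_hi = m + half, n = n)
}

#' Boxplot statistics with the 1.5 IQR outlier rule
#'
#' Median and interquartile range; whiskers extend to the most extreme
#' observations within 1.5 IQR of the quartiles, anything beyond is an
#' outlier.
#'
#' @param values Numeric, at least 2 observations.
#' @return A list with `median`, `q1`, `q3`, `whisker_lo`, `whisker_hi`,
#'   `outliers`, `n`.
#' @export
boxplot_stats <- function(values) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  in_fence <- values >= q[1] - 1.5 * iqr & values <= q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_lo = min(values[in_fence]),
       whisker_hi = max(values[in_fence]),
       outliers = values[!in_fence], n = n)
}
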