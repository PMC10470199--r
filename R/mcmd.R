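#' Experiment plan for the MC-MD protocol
#'
#' Bundles the study conditions of the folding experiments: the polymer
#' layout, the occupancy / attraction / dilution grids, replicate
#' counts, and the per-cycle dynamics length. A cycle represents the
#' characteristic chromatin residence time of PRC1 (about 100 s);
#' `cycle_steps` sets how many MD steps stand in for it, and the
#' full-scale production value is enormous (1e8), so desk-scale plans
#' use shorter cycles and fewer replicates, which preserves the
#' ordering of conditions though absolute ratios shift.
#'
#' @param topo Base `polymer_topology` (default: the 360-mer layout).
#' @param box_side Production box side in \eqn{\sigma} (default sized to
#'   bead volume fraction 0.026).
#' @param pb_values PRC1 occupancy probabilities to scan.
#' @param eps_values Attraction strengths (\eqn{k_BT}) for the affinity
#'   scan.
#' @param dilution_fractions Fractions of methylation *retained* in the
#'   dilution experiment.
#' @param replicates Independent polymers per condition (full scale:
#'   150; 400 for affinity-scan maps).
#' @param cycles Occupancy redraws per replicate.
#' @param cycle_steps MD steps per cycle.
#' @param equil_steps Attraction-free equilibration steps per replicate.
#' @param sample_stride Steps between trajectory samples within a cycle.
#' @param ffp,dp Force-field and dynamics parameter objects.
#' @param seed Master seed; expanded into per-replicate streams.
#' @return An `experiment_plan` list.
#' @export
experiment_plan <- function(topo = build_default(),
                            box_side = round((topo$n_beads / 0.026)^(1 / 3)),
                            pb_values = c(0, 0.25, 0.5, 0.75, 0.9, 1),
                            eps_values = c(0, 2.1, 3.1, 4.1, 5.1, 6.1),
                            dilution_fractions = c(1, 0.75, 0.5),
                            replicates = 10, cycles = 5,
                            cycle_steps = 1e6, equil_steps = 2e5,
                            sample_stride = max(1L, floor(cycle_steps / 20)),
                            ffp = forcefield_params(),
                            dp = dynamics_params(), seed = 1L) {
  stopifnot(all(pb_values >= 0), all(pb_values <= 1),
            all(dilution_fractions >= 0), all(dilution_fractions <= 1),
            replicates >= 2, cycles >= 1, cycle_steps >= 1)
  structure(list(topo = topo, box_side = box_side, pb_values = pb_values,
                 eps_values = eps_values,
                 dilution_fractions = dilution_fractions,
                 replicates = as.integer(replicates),
                 cycles = as.integer(cycles),
                 cycle_steps = as.integer(cycle_steps),
                 equil_steps = as.integer(equil_steps),
                 sample_stride = as.integer(sample_stride),
                 ffp = ffp, dp = dp, seed = as.integer(seed)),
            class = "experiment_plan")
}

#' One Monte Carlo-molecular dynamics cycle
#'
#' Redraws PRC1 occupancy of every PRE with probability `pb_pre`, runs
#' thermostatted dynamics for `n_steps` with occupied PREs attracting
#' methylated beads, samples frames, then clears the occupancy (the
#' PRC1 molecules are considered unbound at cycle end). Repeated calls
#' with redrawn occupancy and pooled samples implement the protocol's
#' averaging over snapshots and PRE assignments.
#'
#' @inheritParams langevin_step
#' @param pb_pre Occupancy probability for this cycle.
#' @param n_steps MD steps in the cycle.
#' @param sample_stride Steps between samples.
#' @param seed Integer seed covering both the occupancy draw and the
#'   noise stream.
#' @return `list(state, frames, n_bound)` where `n_bound` is the number
#'   of PREs occupied during the cycle.
#' @export
mcmd_cycle <- function(state, topo, pb_pre, ffp, dp, n_steps,
                       sample_stride = max(1L, floor(n_steps / 20)),
                       seed = NULL) {
  seeds <- child_seeds(if (is.null(seed)) state$rng_state else seed, 2L)
  topo <- assign_prc1(topo, pb_pre, seed = seeds[1])
  out <- md_run_internal(state, topo, ffp, dp, n_steps, sample_stride,
                         seeds[2])
  out$n_bound <- sum(topo$prc1_bound)
  out$state$rng_state <- as.integer((seeds[2] * 69069 + 12345) %%
                                      2147483647)
  out
}

# Run one replicate: prepare, then `cycles` occupancy redraws; returns
# per-frame locus volumes and pooled frames (locus-restricted if asked).
replicate_run <- function(topo, plan, pb_pre, seed, keep_frames = FALSE) {
  st <- prepare_system(topo, plan$ffp, plan$dp,
                       target_side = plan$box_side,
                       equil_steps = plan$equil_steps, seed = seed)
  idx <- topo$methylated_range[1]:topo$methylated_range[2]
  vols <- numeric(0)
  frames <- list()
  cyc_seeds <- child_seeds(seed + 1L, plan$cycles)
  for (cy in seq_len(plan$cycles)) {
    out <- mcmd_cycle(st, topo, pb_pre, plan$ffp, plan$dp,
                      n_steps = plan$cycle_steps,
                      sample_stride = plan$sample_stride,
                      seed = cyc_seeds[cy])
    st <- out$state
    vols <- c(vols, vapply(out$frames, function(f)
      locus_volume(radius_of_gyration(f, idx)), numeric(1)))
    if (keep_frames) frames <- c(frames, out$frames)
  }
  list(volumes = vols, frames = frames)
}

# Reference volumes from the matching no-PRE layout (occupancy-free).
reference_volumes <- function(plan, seeds) {
  ref_topo <- build_default(n = plan$topo$n_beads, pre_indices = integer(0),
                            methylated_range = plan$topo$methylated_range)
  vapply(seeds, function(s)
    mean(replicate_run(ref_topo, plan, 0, s)$volumes), numeric(1))
}

#' Locus-volume scan over the PRC1 occupancy probability
#'
#' For each `pb_pre` in the plan, `replicates` independent polymers are
#' prepared and cycled through occupancy redraws; the mean locus volume
#' per replicate is divided by the mean reference volume of the no-PRE
#' layout (`Vref`). Folding appears as V/Vref dropping below 1 with
#' increasing occupancy, approaching roughly one half at high
#' occupancy in the full-scale setting.
#'
#' @param plan An [experiment_plan()].
#' @return A list: `summary` (data frame of pb_pre, mean ratio, 95
#'   percent CI), `replicate_ratios` (matrix, replicates x conditions),
#'   `v_ref` (mean reference volume).
#' @export
run_pbpre_scan <- function(plan) {
  seeds <- child_seeds(plan$seed, plan$replicates * (1 + length(plan$pb_values)))
  sm <- matrix(seeds, nrow = plan$replicates)
  vref <- reference_volumes(plan, sm[, 1])
  v_ref <- mean(vref)
  ratios <- matrix(NA_real_, plan$replicates, length(plan$pb_values))
  for (j in seq_along(plan$pb_values)) {
    for (r in seq_len(plan$replicates)) {
      vols <- replicate_run(plan$topo, plan, plan$pb_values[j],
                            sm[r, j + 1])$volumes
      ratios[r, j] <- mean(vols) / v_ref
    }
  }
  summ <- do.call(rbind, lapply(seq_along(plan$pb_values), function(j) {
    ci <- summarize_ci(ratios[, j])
    data.frame(pb_pre = plan$pb_values[j], ratio = ci$mean,
               ci_lo = ci$ci_lo, ci_hi = ci$ci_hi, n = ci$n)
  }))
  list(summary = summ, replicate_ratios = ratios, v_ref = v_ref)
}

#' Pairwise-distance maps across attraction strengths
#'
#' Runs the protocol with PREs permanently occupied (`pb_pre = 1`) at
#' each attraction strength in `plan$eps_values` (0 serves as the
#' negative control) and pools the locus-restricted mean
#' pairwise-distance maps over replicates.
#'
#' @param plan An [experiment_plan()].
#' @return A list: `maps` (named list of `distance_map`s, one per
#'   \eqn{\epsilon}, restricted to the locus), `eps_values`.
#' @export
run_eps_scan <- function(plan) {
  seeds <- child_seeds(plan$seed + 1L,
                       plan$replicates * length(plan$eps_values))
  sm <- matrix(seeds, nrow = plan$replicates)
  idx <- plan$topo$methylated_range[1]:plan$topo$methylated_range[2]
  maps <- vector("list", length(plan$eps_values))
  for (j in seq_along(plan$eps_values)) {
    ff <- plan$ffp
    ff$bind_eps <- plan$eps_values[j]
    sub_plan <- plan
    sub_plan$ffp <- ff
    per_rep <- lapply(seq_len(plan$replicates), function(r) {
      fr <- replicate_run(plan$topo, sub_plan, 1, sm[r, j],
                          keep_frames = TRUE)$frames
      distance_map(fr, indices = idx)
    })
    maps[[j]] <- do.call(pool_distance_maps, per_rep)
  }
  names(maps) <- paste0("eps_", plan$eps_values)
  list(maps = maps, eps_values = plan$eps_values)
}

#' Post-replication dilution experiment
#'
#' For each occupancy probability and each retained-methylation
#' fraction, methylated beads are randomly demethylated before the
#' cycles (a fresh draw per replicate) and the relative locus volume is
#' summarised as boxplot statistics, mirroring the readout used to ask
#' whether folding survives the two-fold post-replication dilution of
#' the H3K27me3 mark.
#'
#' @param plan An [experiment_plan()]; `pb_values` supplies the
#'   occupancy grid (production values 0.89, 0.98, 0.997) and
#'   `dilution_fractions` the retained-methylation grid.
#' @return A list: `summary` (data frame with boxplot statistics per
#'   condition), `ratios` (long data frame of per-replicate ratios),
#'   `v_ref`.
#' @export
run_dilution <- function(plan) {
  conds <- expand.grid(meth_fraction = plan$dilution_fractions,
                       pb_pre = plan$pb_values)
  seeds <- child_seeds(plan$seed + 2L,
                       plan$replicates * (1 + nrow(conds)))
  sm <- matrix(seeds, nrow = plan$replicates)
  v_ref <- mean(reference_volumes(plan, sm[, 1]))
  long <- list()
  for (cc in seq_len(nrow(conds))) {
    keep <- conds$meth_fraction[cc]
    ratios <- vapply(seq_len(plan$replicates), function(r) {
      s <- sm[r, cc + 1]
      topo_r <- demethylate(plan$topo, 1 - keep, seed = s)
      mean(replicate_run(topo_r, plan, conds$pb_pre[cc],
                         s + 1L)$volumes) / v_ref
    }, numeric(1))
    long[[cc]] <- data.frame(pb_pre = conds$pb_pre[cc],
                             meth_fraction = keep,
                             replicate = seq_len(plan$replicates),
                             ratio = ratios)
  }
  long <- do.call(rbind, long)
  summ <- do.call(rbind, lapply(split(long, long[c("meth_fraction",
                                                   "pb_pre")], drop = TRUE),
                                function(d) {
    bs <- boxplot_stats(d$ratio)
    data.frame(pb_pre = d$pb_pre[1], meth_fraction = d$meth_fraction[1],
               median = bs$median, q1 = bs$q1, q3 = bs$q3,
               whisker_lo = bs$whisker_lo, whisker_hi = bs$whisker_hi,
               n = bs$n)
  }))
  rownames(summ) <- NULL
  list(summary = summ, ratios = long, v_ref = v_ref)
}

#' Control layouts: PREs without methylation, methylation without PREs
#'
#' Both controls are run at full occupancy exposure and their relative
#' locus volumes should straddle 1: folding requires both the PREs and
#' the methylated chromatin they bind. Each control replicate is divided
#' by a reference replicate run with its own seed, so the confidence
#' interval reflects the uncertainty of both numerator and reference.
#'
#' @param plan An [experiment_plan()].
#' @param pb_pre Occupancy probability applied to the controls
#'   (default 1).
#' @return A data frame with one row per control (`no_pre`, `no_meth`)
#'   carrying the mean ratio and its 95 percent CI.
#' @export
run_controls <- function(plan, pb_pre = 1) {
  seeds <- child_seeds(plan$seed + 3L, plan$replicates * 3L)
  sm <- matrix(seeds, nrow = plan$replicates)
  vref <- reference_volumes(plan, sm[, 1])
  no_pre <- build_default(n = plan$topo$n_beads, pre_indices = integer(0),
                          methylated_range = plan$topo$methylated_range)
  no_meth <- build_default(n = plan$topo$n_beads,
                           pre_indices = plan$topo$pre_indices,
                           methylated_range = plan$topo$methylated_range,
                           methylated = FALSE)
  res <- list(no_pre = no_pre, no_meth = no_meth)
  out <- list()
  for (k in seq_along(res)) {
    ratios <- vapply(seq_len(plan$replicates), function(r)
      mean(replicate_run(res[[k]], plan, pb_pre,
                         sm[r, k + 1])$volumes) / vref[r], numeric(1))
    ci <- summarize_ci(ratios)
    out[[k]] <- data.frame(control = names(res)[k], ratio = ci$mean,
                           ci_lo = ci$ci_lo, ci_hi = ci$ci_hi, n = ci$n)
  }
  do.call(rbind, out)
}

#' PRE-clustering statistics of folded trajectories
#'
#' Compares the mean 3D distance of PRE-PRE pairs with the background
#' of non-PRE bead pairs at the same linear (index) separation, within
#' the locus. Clustered PREs sit below the background (the
#' off-diagonal-spot signature).
#'
#' @param frames List of coordinate matrices.
#' @param topo A `polymer_topology` with at least two PREs.
#' @return A data frame, one row per PRE pair: indices, linear
#'   separation, mean PRE-PRE distance, background mean at the same
#'   separation, and their difference (negative = closer than
#'   background).
#' @export
pre_pair_vs_background <- function(frames, topo) {
  if (length(topo$pre_indices) < 2) stop("need at least two PREs")
  dm <- unclass(distance_map(frames))
  lo <- topo$methylated_range[1]
  hi <- topo$methylated_range[2]
  pairs <- utils::combn(topo$pre_indices, 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    sep <- j - i
    ii <- lo:(hi - sep)
    jj <- ii + sep
    keep <- !(ii %in% topo$pre_indices) & !(jj %in% topo$pre_indices)
    bg <- mean(dm[cbind(ii[keep], jj[keep])])
    out[[k]] <- data.frame(pre_i = i, pre_j = j, separation = sep,
                           pre_distance = dm[i, j], background = bg,
                           difference = dm[i, j] - bg)
  }
  do.call(rbind, out)
}
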