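#' Build the default three-section polymer layout
#'
#' The chain is divided in three: unmethylated flanks and a central
#' methylated locus (the Polycomb-repressed region) holding a small number
#' of PRE beads. For the default 360-mer the locus spans beads 120--240
#' (1-based, inclusive) and carries four PREs; at 175 bp per nucleosome
#' the chain corresponds to roughly a 63 kb chromatin segment.
#'
#' @param n Number of beads (default 360).
#' @param pre_indices 1-based bead indices of the PREs; must lie inside
#'   `methylated_range` unless `strict = FALSE`. An empty vector yields
#'   the no-PRE control layout.
#' @param methylated_range Inclusive 1-based index interval of the
#'   methylated locus; defaults to the middle third `c(n/3, 2n/3)`.
#' @param strict Enforce that PREs sit inside the methylated range.
#' @param methylated If `FALSE`, leave the central locus unmethylated
#'   (the "PREs without methylation" control layout).
#' @return A `polymer_topology`: bead types (`UNMETH`/`METH`/`PRE`),
#'   per-bead PRC1 occupancy flags (all `FALSE` initially), bond pairs and
#'   angle triplets (consecutive), and the locus interval.
#' @examples
#' topo <- build_default()
#' table(topo$types)
#' @export
build_default <- function(n = 360L,
                          pre_indices = c(132L, 156L, 204L, 228L),
                          methylated_range = c(round(n / 3), round(2 * n / 3)),
                          strict = TRUE, methylated = TRUE) {
  n <- as.integer(n)
  stopifnot(n >= 3, length(methylated_range) == 2,
            methylated_range[1] >= 1, methylated_range[2] <= n)
  pre_indices <- sort(as.integer(pre_indices))
  if (strict && length(pre_indices) &&
      (any(pre_indices < methylated_range[1]) ||
       any(pre_indices > methylated_range[2])))
    stop("PRE indices must lie inside the methylated range [",
         methylated_range[1], ", ", methylated_range[2], "]")
  types <- rep("UNMETH", n)
  if (methylated) types[methylated_range[1]:methylated_range[2]] <- "METH"
  types[pre_indices] <- "PRE"
  new_topology(types, pre_indices, methylated_range)
}

new_topology <- function(types, pre_indices, methylated_range) {
  n <- length(types)
  structure(list(
    n_beads = n,
    types = types,
    prc1_bound = rep(FALSE, n),
    pre_indices = as.integer(pre_indices),
    methylated_range = as.integer(methylated_range),
    bonds = if (n >= 2) cbind(seq_len(n - 1L), seq.int(2L, n)) else
      matrix(integer(), 0, 2),
    angles = if (n >= 3) cbind(seq_len(n - 2L), seq.int(2L, n - 1L),
                               seq.int(3L, n)) else
      matrix(integer(), 0, 3)
  ), class = "polymer_topology")
}

#' @export
print.polymer_topology <- function(x, ...) {
  cat(sprintf("<polymer_topology> %d beads | locus [%d, %d] | %d PRE(s)",
              x$n_beads, x$methylated_range[1], x$methylated_range[2],
              length(x$pre_indices)))
  if (length(x$pre_indices))
    cat(" at", paste(x$pre_indices, collapse = ", "))
  cat(sprintf(" | %d bound\n", sum(x$prc1_bound)))
  invisible(x)
}

#' Reposition PREs at given fractions of the locus length
#'
#' Emulates loci such as *invected-engrailed* in which PREs sit near the
#' edges of the Polycomb-repressed domain: each PRE is placed at
#' `lo + round(f * (hi - lo))` for a fraction `f` of the methylated
#' interval `[lo, hi]`. The default fractions place two PREs near each
#' locus edge; they are read-from-map approximations and fully
#' configurable.
#'
#' @param relative_positions Strictly increasing fractions in (0, 1).
#' @inheritParams build_default
#' @return A `polymer_topology`.
#' @examples
#' build_inv_en()
#' @export
build_inv_en <- function(relative_positions = c(0.02, 0.10, 0.90, 0.98),
                         n = 360L,
                         methylated_range = c(round(n / 3), round(2 * n / 3))) {
  f <- relative_positions
  stopifnot(length(f) >= 1, all(f > 0), all(f < 1))
  if (is.unsorted(f, strictly = TRUE))
    stop("relative_positions must be strictly increasing")
  lo <- methylated_range[1]
  hi <- methylated_range[2]
  idx <- as.integer(lo + round(f * (hi - lo)))
  build_default(n = n, pre_indices = idx, methylated_range = methylated_range)
}

#' Randomly demethylate a fraction of the locus
#'
#' Mimics post-replication dilution of the H3K27me3 mark: exactly
#' `round(fraction * n_meth)` methylated beads (round half up), chosen
#' uniformly, become unmethylated. PRE beads are never touched.
#'
#' @param topo A `polymer_topology`.
#' @param fraction_replaced Fraction of methylated beads to replace, in
#'   \[0, 1\]. 0.5 emulates the state right after DNA replication.
#' @param seed Optional integer seed for a reproducible draw.
#' @return A `polymer_topology` with reduced methylation.
#' @export
demethylate <- function(topo, fraction_replaced, seed = NULL) {
  stopifnot(fraction_replaced >= 0, fraction_replaced <= 1)
  meth <- which(topo$types == "METH")
  k <- floor(fraction_replaced * length(meth) + 0.5)
  if (k > 0) {
    drop <- with_seed(seed, sample(meth, k))
    topo$types[drop] <- "UNMETH"
  }
  topo
}

#' Monte Carlo assignment of PRC1 occupancy to PREs
#'
#' Each PRE is independently set to the PRC1-bound state with probability
#' `pb_pre` (one uniform draw per PRE, in ascending bead-index order).
#' Occupied PREs feel the binding attraction to methylated beads during
#' the following dynamics round; calling this again redraws the occupancy,
#' which is the Monte Carlo half of the MC-MD protocol.
#'
#' @param topo A `polymer_topology`.
#' @param pb_pre Binding probability in \[0, 1\]; relates to the PRC1
#'   concentration and PRE dissociation constant through [pb_bound()].
#' @param seed Optional integer seed.
#' @return The topology with updated `prc1_bound` flags.
#' @export
assign_prc1 <- function(topo, pb_pre, seed = NULL) {
  stopifnot(pb_pre >= 0, pb_pre <= 1)
  topo$prc1_bound[] <- FALSE
  if (length(topo$pre_indices)) {
    r <- with_seed(seed, runif(length(topo$pre_indices)))
    topo$prc1_bound[topo$pre_indices] <- r < pb_pre
  }
  topo
}

#' Serialize / read a topology as a plain-text table
#'
#' Three columns: 1-based bead index, type label, PRC1-bound flag.
#'
#' @param topo A `polymer_topology`.
#' @param path File path.
#' @return `read_topology()` returns a `polymer_topology`;
#'   `write_topology()` returns `path` invisibly.
#' @export
write_topology <- function(topo, path) {
  df <- data.frame(index = seq_len(topo$n_beads), type = topo$types,
                   bound = topo$prc1_bound)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("index", "type", "bound") %in% names(df)))
  df <- df[order(df$index), ]
  pre <- df$index[df$type == "PRE"]
  core <- df$index[df$type %in% c("METH", "PRE")]
  meth <- if (length(core)) range(core) else c(0L, -1L)
  topo <- new_topology(df$type, pre, meth)
  topo$prc1_bound <- as.logical(df$bound)
  if (any(topo$prc1_bound & df$type != "PRE"))
    stop("only PRE beads may carry a PRC1-bound flag")
  topo
}
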