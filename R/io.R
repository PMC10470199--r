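#' Default run configuration
#'
#' The resolved defaults mirror the production study conditions:
#' FENE Ks = 30 kBT, R0 = 1.5 sigma, bending Ktheta = 3 kBT, WCA
#' eps_ev = 1 kBT, attraction eps = 5.1 kBT with range 2.5 sigma,
#' damping 0.5 / tau, step 0.012 tau, a 360-mer in a 24 sigma box.
#'
#' @return A nested list with `forcefield`, `dynamics`, `topology`,
#'   `experiment`, `output_dir`, `seed`, `scale` blocks.
#' @export
default_config <- function() {
  list(
    forcefield = list(fene_k = 30, fene_r0 = 1.5, bend_k = 3, ev_eps = 1,
                      bind_eps = 5.1, bind_cutoff = 2.5, soft_amp = 40,
                      soft_cutoff = 2.5, sigma_nm = 10),
    dynamics = list(kBT = 1, mass = 1, gamma = 0.5, dt = 0.012,
                    diffusion = 5, sigma_nm = 10, seed = 1L),
    topology = list(n_beads = 360L, pre_indices = c(132L, 156L, 204L, 228L),
                    methylated_range = c(120L, 240L)),
    experiment = list(box_side = 24, pb_values = c(0, 0.25, 0.5, 0.75,
                                                   0.9, 1),
                      eps_values = c(0, 2.1, 3.1, 4.1, 5.1, 6.1),
                      dilution_fractions = c(1, 0.75, 0.5),
                      replicates = 10L, cycles = 5L, cycle_steps = 1e6,
                      equil_steps = 2e5),
    output_dir = ".",
    seed = 1L,
    scale = 1
  )
}

check_keys <- function(given, reference, path = "") {
  extra <- setdiff(names(given), names(reference))
  if (length(extra))
    stop("unknown configuration key: ", path, extra[1])
  for (k in names(given)) {
    if (is.list(reference[[k]]) && !is.null(names(reference[[k]])))
      check_keys(as.list(given[[k]]), reference[[k]], paste0(path, k, "$"))
  }
}

#' Load / save a run configuration
#'
#' JSON or YAML keyed by file extension. Missing blocks and fields are
#' filled from [default_config()]; unknown keys are rejected by name so
#' typos cannot silently fall back to defaults. An empty file yields the
#' full default configuration.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @param cfg A configuration list (for `save_config`).
#' @return `load_config()` returns the resolved configuration list;
#'   `save_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    if (file.info(path)$size == 0) list() else
      jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  } else stop("unsupported config format: .", ext)
  defaults <- default_config()
  check_keys(raw, defaults)
  cfg <- modifyList(defaults, raw)
  cfg$topology$n_beads <- as.integer(cfg$topology$n_beads)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else stop("unsupported config format: .", ext)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' @param cfg A configuration list as returned by [load_config()].
#' @return A list with `ffp`, `dp`, `topo` ready for the simulation
#'   functions.
#' @export
config_objects <- function(cfg) {
  ff <- cfg$forcefield
  dyn <- cfg$dynamics
  tp <- cfg$topology
  list(
    ffp = forcefield_params(fene_k = ff$fene_k, fene_r0 = ff$fene_r0,
                            bend_k = ff$bend_k, ev_eps = ff$ev_eps,
                            bind_eps = ff$bind_eps,
                            bind_cutoff = ff$bind_cutoff,
                            soft_amp = ff$soft_amp,
                            soft_cutoff = ff$soft_cutoff,
                            sigma_nm = ff$sigma_nm),
    dp = dynamics_params(kBT = dyn$kBT, mass = dyn$mass, gamma = dyn$gamma,
                         dt = dyn$dt, diffusion = dyn$diffusion,
                         sigma_nm = dyn$sigma_nm, seed = dyn$seed),
    topo = build_default(n = tp$n_beads, pre_indices = tp$pre_indices,
                         methylated_range = tp$methylated_range)
  )
}

type_labels <- function(topo) {
  lab <- topo$types
  lab[topo$prc1_bound] <- "PREB"
  lab
}

#' Write / read an XYZ trajectory
#'
#' Plain-text XYZ: per frame a bead count line, a comment line carrying
#' `step=`, `time_us=` and `box=`, then one `LABEL x y z` record per
#' bead (coordinates in \eqn{\sigma}). Labels are the bead types, with
#' `PREB` marking PRC1-bound PREs. Read and write round-trip to float
#' precision.
#'
#' @param frames List of `n x 3` matrices with `step`/`time_us`/
#'   `box_side` attributes (as produced by [run_dynamics()]).
#' @param path Output file.
#' @param topo Optional `polymer_topology` supplying type labels
#'   (default: every bead labelled `BEAD`).
#' @return `write_trajectory()` returns `path` invisibly;
#'   `read_trajectory()` returns the frame list with a `types`
#'   attribute.
#' @export
write_trajectory <- function(frames, path, topo = NULL) {
  stopifnot(length(frames) >= 1)
  n <- nrow(frames[[1]])
  labels <- if (is.null(topo)) rep("BEAD", n) else type_labels(topo)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    stopifnot(nrow(f) == n)
    writeLines(as.character(n), con)
    writeLines(sprintf("step=%d time_us=%.6g box=%.10g",
                       as.integer(attr(f, "step") %||% 0),
                       attr(f, "time_us") %||% 0,
                       attr(f, "box_side") %||% 0), con)
    writeLines(sprintf("%s %.10g %.10g %.10g", labels,
                       f[, 1], f[, 2], f[, 3]), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed XYZ header at line ", i)
    meta <- lines[i + 1L]
    grab <- function(key) {
      m <- regmatches(meta, regexec(paste0(key, "=([^ ]+)"), meta))[[1]]
      if (length(m) < 2) NA_real_ else as.numeric(m[2])
    }
    rec <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(rec, "\\s+")
    bad <- which(lengths(parts) != 4)
    if (length(bad))
      stop("malformed XYZ record at line ", i + 1L + bad[1])
    m <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                ncol = 3, byrow = TRUE)
    attr(m, "step") <- as.integer(grab("step"))
    attr(m, "time_us") <- grab("time_us")
    attr(m, "box_side") <- grab("box")
    attr(m, "types") <- vapply(parts, `[`, character(1), 1)
    frames[[length(frames) + 1L]] <- m
    i <- i + 2L + n
  }
  frames
}

#' Deterministic miniature systems for tests and examples
#'
#' * `chain60`: 60-mer with a 20-bead methylated core (beads 21--40) and
#'   two PREs (26, 34); the desk-scale stand-in for the 360-mer.
#' * `dimer-overlap`: two bonded beads 0.5 sigma apart, for push-off
#'   checks.
#' * `calibration-box-small`: 50 binder particles and one site in a box
#'   sized to a 5 uM-equivalent concentration.
#' * `loop-configs`: the three anchored-loop configurations.
#'
#' @param kind One of the fixture names above.
#' @param seed Integer seed for any randomness.
#' @return A list whose elements depend on `kind` (topology and/or
#'   state, or loop specs).
#' @export
make_fixture <- function(kind, seed = 1L) {
  switch(kind,
    "chain60" = {
      topo <- build_default(n = 60L, pre_indices = c(26L, 34L),
                            methylated_range = c(21L, 40L))
      list(topo = topo)
    },
    "dimer-overlap" = {
      topo <- new_topology(c("UNMETH", "UNMETH"), integer(0), c(0L, -1L))
      pos <- rbind(c(0, 0, 0), c(0.5, 0, 0))
      list(topo = topo,
           state = system_state(pos, box_side = 20, seed = seed))
    },
    "calibration-box-small" = {
      side <- box_side_for_concentration(50, 5e-6)
      list(setup = calibration_setup(n_particles = 50, box_side = side,
                                     frames = 100, replicates = 2,
                                     stride = 2000, burnin_steps = 5000))
    },
    "loop-configs" = {
      lapply(1:3, loop_model_config, seed = seed)
    },
    stop("unknown fixture kind: ", kind)
  )
}
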