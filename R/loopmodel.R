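#' Anchored-loop model of PRE clustering
#'
#' A one-dimensional caricature of why PREs cluster when the methylated
#' locus folds. Each PRE is an anchor point on a line that throws loops
#' whose lengths follow a Gaussian centred at the anchor position with
#' standard deviation `sigma_l`. Only loops landing on "sticky"
#' (methylated) chromatin persist, so an anchor flanked by non-sticky
#' chromatin on one side draws from a half-Gaussian restricted to the
#' sticky side. The mean absolute distance between the two anchors'
#' loop positions measures how close the anchors appear:
#' it equals the linear separation when both anchors loop freely and
#' shrinks as anchors become inward-restricted.
#'
#' @param anchor_positions Numeric length-2, the anchor coordinates
#'   (default 0 and 2).
#' @param sigma_l Loop-length standard deviation (> 0). The default 0.3
#'   is the value consistent with the reference mean distances 1.76 and
#'   1.52 for the restricted configurations (0.2 yields 1.84 / 1.68).
#' @param directionality Character length-2, each of `"both"`,
#'   `"right-only"`, `"left-only"`: the side(s) towards which the anchor
#'   may form long-lived loops.
#' @param n_draws Monte Carlo sample size (default 1e4).
#' @param seed Optional integer seed.
#' @return A `loop_model_spec` list.
#' @examples
#' spec <- loop_model_spec(directionality = c("right-only", "left-only"))
#' mean_anchor_distance(spec, seed = 1)
#' @export
loop_model_spec <- function(anchor_positions = c(0, 2), sigma_l = 0.3,
                            directionality = c("both", "both"),
                            n_draws = 1e4, seed = NULL) {
  stopifnot(length(anchor_positions) == 2,
            anchor_positions[1] != anchor_positions[2],
            sigma_l > 0, n_draws >= 1,
            length(directionality) == 2,
            all(directionality %in% c("both", "right-only", "left-only")))
  structure(list(anchor_positions = anchor_positions, sigma_l = sigma_l,
                 directionality = directionality,
                 n_draws = as.integer(n_draws), seed = seed),
            class = "loop_model_spec")
}

#' Predefined anchor/stickiness configurations
#'
#' Configuration 1: sticky chromatin on all sides, both anchors loop
#' freely. Configuration 2: the left flank is non-sticky, so the left
#' anchor loops rightward only. Configuration 3: only the segment
#' between the anchors is sticky, both anchors loop inward.
#'
#' @param config Integer 1, 2 or 3.
#' @inheritParams loop_model_spec
#' @return A `loop_model_spec`.
#' @export
loop_model_config <- function(config, sigma_l = 0.3, n_draws = 1e4,
                              seed = NULL) {
  dir <- switch(as.character(config),
                "1" = c("both", "both"),
                "2" = c("right-only", "both"),
                "3" = c("right-only", "left-only"),
                stop("config must be 1, 2 or 3"))
  loop_model_spec(directionality = dir, sigma_l = sigma_l,
                  n_draws = n_draws, seed = seed)
}

#' Draw loop lengths for both anchors
#'
#' Unrestricted anchors draw from the full Gaussian centred at their
#' position; restricted anchors from the half-Gaussian on the allowed
#' side (sampled as position plus/minus the absolute value of a centred
#' normal, which is distribution-identical to rejection sampling).
#'
#' @param spec A [loop_model_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return An `n_draws x 2` matrix of loop endpoint positions.
#' @export
sample_loop_lengths <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    draws <- vapply(1:2, function(k) {
      l0 <- spec$anchor_positions[k]
      z <- rnorm(spec$n_draws, 0, spec$sigma_l)
      switch(spec$directionality[k],
             "both" = l0 + z,
             "right-only" = l0 + abs(z),
             "left-only" = l0 - abs(z))
    }, numeric(spec$n_draws))
    colnames(draws) <- c("l1", "l2")
    draws
  })
}

#' Monte Carlo mean absolute anchor distance
#'
#' Draws `n_draws` loop pairs and averages \eqn{\Delta = |l_1 - l_2|}.
#'
#' @inheritParams sample_loop_lengths
#' @return A named list: `mean` (the Monte Carlo estimate), `se`
#'   (standard error), `n`.
#' @export
mean_anchor_distance <- function(spec, seed = spec$seed) {
  l <- sample_loop_lengths(spec, seed = seed)
  d <- abs(l[, 1] - l[, 2])
  list(mean = mean(d), se = sd(d) / sqrt(length(d)), n = length(d))
}

#' Closed-form mean anchor distance (no-sign-flip limit)
#'
#' When the anchor separation L is large compared to `sigma_l`, the two
#' loop endpoints almost never cross, so
#' \eqn{\bar\Delta = L - k\,\sigma_l \sqrt{2/\pi}} with k the number of
#' inward-restricted anchors (each half-Gaussian shifts its endpoint
#' inward by the half-normal mean \eqn{\sigma_l\sqrt{2/\pi}}). Serves as
#' the analytic oracle for [mean_anchor_distance()].
#'
#' @param spec A [loop_model_spec()].
#' @return \eqn{\bar\Delta} in line units.
#' @examples
#' closed_form_mean(loop_model_config(3)) # 2 - 2 * 0.3 * sqrt(2 / pi)
#' @export
closed_form_mean <- function(spec) {
  L <- abs(diff(spec$anchor_positions))
  if (L < 4 * spec$sigma_l)
    warning("anchors closer than 4 sigma_l; closed form degrades")
  left <- which.min(spec$anchor_positions)
  right <- 3 - left
  k <- (spec$directionality[left] == "right-only") +
       (spec$directionality[right] == "left-only")
  L - k * spec$sigma_l * sqrt(2 / pi)
}
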