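# Behavioural experiment runners: two-target saccade choice, preference maps,
# strike sweeps. Every run is reproducible from (config arguments, seed), and
# summaries are plain re-aggregations of the per-trial rows.

#' Two-target scene
#'
#' Two spheres at mirrored azimuths and equal elevation, each subtending the
#' same angle at the origin but at (generally) different distances. Defaults
#' reproduce the standard two-target choice condition: targets at -15 and +15
#' degrees azimuth, at 4 and 8 cm, both subtending 15 degrees (diameters 1.1
#' and 2.1 cm).
#'
#' @param azimuths Length-2 target azimuths in degrees.
#' @param distances Length-2 target distances in cm.
#' @param subtenses Angular subtense(s) at the origin in degrees; length 1 or
#'   2.
#' @param elevation Common elevation in degrees.
#' @return A [scene()].
#' @export
two_target_scene <- function(azimuths = c(-15, 15), distances = c(4, 8),
                             subtenses = 15, elevation = 0) {
  stopifnot(length(azimuths) == 2, length(distances) == 2)
  subtenses <- rep(subtenses, length.out = 2)
  scene(
    azimuth = azimuths,
    elevation = rep(elevation, 2),
    distance = distances,
    diameter = sphere_diameter_for_subtense(distances, subtenses)
  )
}

# Internal: flattened noise-free input vector for a scene.
.scene_input <- function(scene, net, pose = head_pose()) {
  g <- net$input_grid
  u <- .grid_unit_vectors(g)
  c(.render_values(scene, pose, "left", g, u),
    .render_values(scene, pose, "right", g, u))
}

# Internal: n_repeats winner indices for a scene under per-repeat clipped
# Gaussian noise (independent across eyes and repeats).
.noisy_decisions <- function(net, scene, n_repeats, noise_sigma,
                             pose = head_pose()) {
  x0 <- .scene_input(scene, net, pose)
  x <- matrix(x0, length(x0), n_repeats)
  if (noise_sigma > 0) {
    x <- pmax(x + matrix(stats::rnorm(length(x), 0, noise_sigma), nrow(x)), 0)
  }
  .decide_batch(net, x)
}

#' Two-target saccade experiment
#'
#' Presents the two-target scene to a trained network for `n_repeats` noisy
#' repeats and records every saccade decision. The summary attributes report
#' the mean and s.d. of the saccade azimuth and the proportion of saccades
#' towards the nearer target's side.
#'
#' @param net A trained [saccade_network()].
#' @param azimuths,distances,subtenses,elevation Scene parameters, see
#'   [two_target_scene()].
#' @param n_repeats Number of noisy presentations.
#' @param noise_sigma Clipped-Gaussian noise s.d. (see [add_noise()]).
#' @param seed Optional integer seed.
#' @return A data frame of class `result_table`, one row per trial, with
#'   columns `repeat_index`, `azimuth`, `elevation`, `no_action`,
#'   `chose_nearer`; attributes `mean_azimuth`, `sd_azimuth`, `prop_nearer`
#'   and `config`.
#' @export
run_two_target_experiment <- function(net, azimuths = c(-15, 15),
                                      distances = c(4, 8), subtenses = 15,
                                      elevation = 0, n_repeats = 1000,
                                      noise_sigma = 0.1, seed = NULL) {
  stopifnot(inherits(net, "saccade_network"))
  if (!net$trained) stop("the saccade network must be trained first")
  if (!is.null(seed)) set.seed(seed)
  sc <- two_target_scene(azimuths, distances, subtenses, elevation)
  winners <- .noisy_decisions(net, sc, n_repeats, noise_sigma)
  g <- net$output_grid
  ia <- (winners - 1L) %/% g$n_elevation + 1L
  ie <- (winners - 1L) %% g$n_elevation + 1L
  zero <- .nearest_grid_cell(g, 0, 0)$index
  nearer_sign <- sign(azimuths[which.min(distances)])
  out <- data.frame(
    repeat_index = seq_len(n_repeats),
    azimuth = g$azimuths[ia],
    elevation = g$elevations[ie],
    no_action = winners == zero,
    chose_nearer = sign(g$azimuths[ia]) == nearer_sign
  )
  attr(out, "mean_azimuth") <- mean(out$azimuth)
  attr(out, "sd_azimuth") <- stats::sd(out$azimuth)
  attr(out, "prop_nearer") <- mean(out$chose_nearer)
  attr(out, "config") <- list(azimuths = azimuths, distances = distances,
                              subtenses = subtenses, elevation = elevation,
                              n_repeats = n_repeats, noise_sigma = noise_sigma,
                              seed = seed)
  class(out) <- c("result_table", "data.frame")
  out
}

#' Near-target preference map
#'
#' For every cell of a condition grid, the proportion of saccades towards the
#' nearer of two mirrored targets at +/-15 degrees azimuth.
#'
#' With `mode = "distances"`, both targets subtend `subtense` degrees and the
#' grid spans left-target distance x right-target distance. With
#' `mode = "sizes"`, the distances are fixed (default 8 cm left, 4 cm right)
#' and the grid spans left-target subtense x right-target subtense.
#'
#' @param net A trained [saccade_network()].
#' @param mode `"distances"` or `"sizes"`.
#' @param left_values,right_values Condition values for the left and right
#'   target (distances in cm, or subtenses in degrees, by mode).
#' @param distances `"sizes"` mode only: fixed length-2 distances (left,
#'   right) in cm.
#' @param subtense `"distances"` mode only: common angular subtense in
#'   degrees.
#' @param n_repeats Noisy repeats per cell.
#' @param noise_sigma Noise s.d.
#' @param seed Optional integer seed.
#' @return A data frame of class `result_table` with one row per condition:
#'   `left_value`, `right_value`, `nearer_side`, `prop_nearer`,
#'   `prop_no_action`.
#' @export
run_preference_map <- function(net, mode = c("distances", "sizes"),
                               left_values = NULL, right_values = NULL,
                               distances = c(8, 4), subtense = 10,
                               n_repeats = 200, noise_sigma = 0.1,
                               seed = NULL) {
  stopifnot(inherits(net, "saccade_network"))
  if (!net$trained) stop("the saccade network must be trained first")
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(left_values)) {
    left_values <- if (mode == "distances") seq(2, 10, by = 2) else
      seq(5, 25, by = 5)
  }
  if (is.null(right_values)) right_values <- left_values
  grid_cells <- expand.grid(left_value = left_values,
                            right_value = right_values,
                            KEEP.OUT.ATTRS = FALSE)
  g <- net$output_grid
  zero <- .nearest_grid_cell(g, 0, 0)$index
  rows <- lapply(seq_len(nrow(grid_cells)), function(i) {
    lv <- grid_cells$left_value[i]
    rv <- grid_cells$right_value[i]
    if (mode == "distances") {
      sc <- two_target_scene(distances = c(lv, rv), subtenses = subtense)
      dists <- c(lv, rv)
    } else {
      sc <- two_target_scene(distances = distances, subtenses = c(lv, rv))
      dists <- distances
    }
    nearer_sign <- sign(c(-15, 15)[which.min(dists)])
    winners <- .noisy_decisions(net, sc, n_repeats, noise_sigma)
    ia <- (winners - 1L) %/% g$n_elevation + 1L
    az <- g$azimuths[ia]
    data.frame(left_value = lv, right_value = rv,
               nearer_side = if (nearer_sign < 0) "left" else "right",
               prop_nearer = mean(sign(az) == nearer_sign),
               prop_no_action = mean(winners == zero))
  })
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(mode = mode, distances = distances,
                              subtense = subtense, n_repeats = n_repeats,
                              noise_sigma = noise_sigma, seed = seed)
  class(out) <- c("result_table", "data.frame")
  out
}

#' Strike-sensor stimulus sweeps
#'
#' Three sweeps over the strike sensor's stimulus space:
#' \describe{
#'   \item{`size`}{diameter x distance grid of moving discs; mean activity is
#'     size-tuned, peaking near the RF centre's angular size at the preferred
#'     distance.}
#'   \item{`vertical`}{vertical dichoptic offset x diameter; activity collapses
#'     at an offset set by the excitatory-centre size, independent of
#'     diameter.}
#'   \item{`ghost`}{ghost pair versus the matched single near object.}
#' }
#'
#' @param sensor A [strike_sensor()].
#' @param preproc A [monocular_preproc()]; defaults to the sensor's.
#' @param subtenses Angular sizes (degrees, at each tested distance) for the
#'   size sweep.
#' @param distances Distances (cm) for the size sweep.
#' @param offsets Vertical offsets (degrees) for the vertical sweep.
#' @param vertical_subtenses Angular sizes for the vertical sweep.
#' @param ghost_far_distance Far-sphere distance (cm from each eye) for the
#'   ghost condition.
#' @param seed Optional integer seed for strike sampling.
#' @return A named list of `result_table` data frames: `size`, `vertical`,
#'   `ghost`. Each row carries the condition, `mean_activity` and
#'   `strike_count`.
#' @export
run_strike_sweeps <- function(sensor, preproc = sensor$preproc,
                              subtenses = c(4, 6, 8, 10, 12, 16, 20),
                              distances = NULL,
                              offsets = seq(0, 16, by = 2),
                              vertical_subtenses = c(10, 20),
                              ghost_far_distance = 5, seed = NULL) {
  stopifnot(inherits(sensor, "strike_sensor"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(distances)) {
    distances <- sensor$preferred_distance * c(0.5, 1, 2)
  }
  grid <- sensor$grid
  one <- function(stim, extra) {
    act <- trial_activity(stim, sensor, preproc)
    cbind(extra, data.frame(mean_activity = mean(act),
                            strike_count = sample_strikes(act, sensor$gain)))
  }
  size <- do.call(rbind, lapply(distances, function(d) {
    do.call(rbind, lapply(subtenses, function(s) {
      stim <- build_stimulus("moving_disc", distance = d,
                             diameter = sphere_diameter_for_subtense(d, s),
                             grid = grid, interocular = sensor$interocular)
      one(stim, data.frame(distance = d, subtense = s))
    }))
  }))
  vertical <- do.call(rbind, lapply(vertical_subtenses, function(s) {
    do.call(rbind, lapply(offsets, function(o) {
      stim <- build_stimulus("vertical_disparity",
                             distance = sensor$preferred_distance,
                             diameter = sphere_diameter_for_subtense(
                               sensor$preferred_distance, s),
                             offset = o, grid = grid,
                             interocular = sensor$interocular)
      one(stim, data.frame(subtense = s, offset = o))
    }))
  }))
  ghost <- do.call(rbind, lapply(c("moving_disc", "ghost_pair"), function(k) {
    stim <- build_stimulus(k, distance = sensor$preferred_distance,
                           far_distance = ghost_far_distance, grid = grid,
                           interocular = sensor$interocular)
    one(stim, data.frame(condition = if (k == "moving_disc") "real" else
      "ghost"))
  }))
  out <- list(size = size, vertical = vertical, ghost = ghost)
  out <- lapply(out, function(t) {
    class(t) <- c("result_table", "data.frame")
    t
  })
  attr(out, "config") <- list(subtenses = subtenses, distances = distances,
                              offsets = offsets,
                              vertical_subtenses = vertical_subtenses,
                              ghost_far_distance = ghost_far_distance,
                              seed = seed)
  out
}

#' Half-response vertical-disparity offset
#'
#' Linearly interpolated offset at which mean activity first falls below half
#' its zero-offset value, from a `vertical` sweep table.
#'
#' @param sweep The `vertical` component of [run_strike_sweeps()] output,
#'   filtered to one subtense.
#' @return Offset in degrees (`NA` if activity never falls below half).
#' @export
half_response_offset <- function(sweep) {
  stopifnot(all(c("offset", "mean_activity") %in% names(sweep)))
  sweep <- sweep[order(sweep$offset), ]
  a0 <- sweep$mean_activity[sweep$offset == min(sweep$offset)][1]
  if (a0 <= 0) return(NA_real_)
  half <- a0 / 2
  below <- which(sweep$mean_activity < half)
  if (length(below) == 0) return(NA_real_)
  i <- below[1]
  if (i == 1) return(sweep$offset[1])
  x0 <- sweep$offset[i - 1]; y0 <- sweep$mean_activity[i - 1]
  x1 <- sweep$offset[i]; y1 <- sweep$mean_activity[i]
  x0 + (half - y0) * (x1 - x0) / (y1 - y0)
}
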