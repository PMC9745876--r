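# Single centre-surround disparity sensor for strike triggering.
#
# Pipeline per eye: spatial low-pass (sparse ommatidial sampling), first-order
# temporal high-pass, full-wave rectification; then the inner product with a
# centre/surround receptive-field window gives the monocular drive. The two
# drives are summed, thresholded and raised to an expansive power; strike
# probability per frame is proportional to the instantaneous activity.

#' Monocular preprocessing parameters
#'
#' @param spatial_sigma S.d. of the isotropic Gaussian spatial low-pass, in
#'   degrees.
#' @param time_constant Time constant of the first-order temporal high-pass,
#'   in seconds.
#' @return A list of class `monocular_preproc`.
#' @export
monocular_preproc <- function(spatial_sigma = 1, time_constant = 0.2) {
  stopifnot(spatial_sigma > 0, time_constant > 0)
  structure(list(spatial_sigma = spatial_sigma, time_constant = time_constant),
            class = "monocular_preproc")
}

# Internal: row-normalized Gaussian blur matrix for one axis.
.blur_matrix <- function(n, sigma_units) {
  i <- seq_len(n)
  m <- outer(i, i, function(a, b) exp(-(a - b)^2 / (2 * sigma_units^2)))
  m / rowSums(m)
}

#' Monocular preprocessing of an image sequence
#'
#' Applies, per frame, an isotropic Gaussian spatial low-pass (edge
#' re-normalized), then a first-order temporal high-pass
#' `y_t = a * (y_{t-1} + x_t - x_{t-1})` with `a = tau / (tau + dt)` and
#' `y_1 = 0`, then full-wave rectification. A static sequence maps to zero
#' drive; inverting the contrast sign of the input leaves the output unchanged.
#'
#' @param sequence A numeric 3D array, `n_elevation x n_azimuth x n_frames`,
#'   with at least 2 frames.
#' @param preproc A [monocular_preproc()].
#' @param grid The [retinal_grid()] the frames are sampled on (sets the
#'   deg-to-unit conversion of the spatial scale).
#' @param frame_interval Frame interval in seconds.
#' @return A 3D array of rectified drive, same shape as the input.
#' @export
preprocess <- function(sequence, preproc, grid, frame_interval = 0.01) {
  stopifnot(inherits(preproc, "monocular_preproc"),
            inherits(grid, "retinal_grid"),
            is.array(sequence), length(dim(sequence)) == 3,
            dim(sequence)[1] == grid$n_elevation,
            dim(sequence)[2] == grid$n_azimuth,
            frame_interval > 0)
  n_frames <- dim(sequence)[3]
  if (n_frames < 2) stop("preprocessing needs at least 2 frames")
  b_el <- .blur_matrix(grid$n_elevation,
                       preproc$spatial_sigma / diff(grid$elevations[1:2]))
  b_az <- .blur_matrix(grid$n_azimuth,
                       preproc$spatial_sigma / diff(grid$azimuths[1:2]))
  lp <- sequence
  for (t in seq_len(n_frames)) {
    lp[, , t] <- b_el %*% sequence[, , t] %*% t(b_az)
  }
  a <- preproc$time_constant / (preproc$time_constant + frame_interval)
  out <- array(0, dim(sequence))
  prev_y <- matrix(0, dim(sequence)[1], dim(sequence)[2])
  for (t in 2:n_frames) {
    prev_y <- a * (prev_y + lp[, , t] - lp[, , t - 1])
    out[, , t] <- prev_y
  }
  abs(out)
}

#' Centre-surround receptive field
#'
#' A binary-annulus window on a retinal grid: cells within `centre_radius`
#' (angular distance from the centre direction) get `centre_weight`, cells in
#' the annulus up to `surround_radius` get `surround_weight`, all others zero.
#' By default the surround weight balances the centre so that a full-field
#' stimulus produces zero drive.
#'
#' @param eye `"left"` or `"right"`.
#' @param centre_azimuth,centre_elevation RF centre direction in degrees
#'   (nasal offsets: negative azimuth for the left eye, positive for the
#'   right).
#' @param centre_radius,surround_radius Angular radii in degrees;
#'   `surround_radius > centre_radius`.
#' @param centre_weight Positive weight of centre cells.
#' @param surround_weight Negative weight of surround cells; default balances
#'   the centre exactly.
#' @param grid A [retinal_grid()].
#' @return An object of class `centre_surround_rf` carrying the window matrix.
#' @export
centre_surround_rf <- function(eye = c("left", "right"),
                               centre_azimuth, centre_elevation = 0,
                               centre_radius = 5, surround_radius = 10,
                               centre_weight = 1, surround_weight = NULL,
                               grid = strike_grid()) {
  eye <- match.arg(eye)
  stopifnot(surround_radius > centre_radius, centre_radius > 0,
            centre_weight > 0, inherits(grid, "retinal_grid"))
  u <- .grid_unit_vectors(grid)
  a <- .deg2rad(centre_azimuth)
  k <- .deg2rad(centre_elevation)
  c_dir <- c(cos(k) * sin(a), sin(k), cos(k) * cos(a))
  ang <- .rad2deg(acos(pmax(-1, pmin(1, as.numeric(u %*% c_dir)))))
  in_centre <- ang <= centre_radius
  in_surround <- ang > centre_radius & ang <= surround_radius
  if (is.null(surround_weight)) {
    surround_weight <- if (any(in_surround)) {
      -centre_weight * sum(in_centre) / sum(in_surround)
    } else {
      -centre_weight
    }
  }
  stopifnot(surround_weight < 0)
  w <- numeric(length(ang))
  w[in_centre] <- centre_weight
  w[in_surround] <- surround_weight
  structure(
    list(eye = eye, centre_azimuth = centre_azimuth,
         centre_elevation = centre_elevation, centre_radius = centre_radius,
         surround_radius = surround_radius, centre_weight = centre_weight,
         surround_weight = surround_weight, grid = grid,
         window = matrix(w, grid$n_elevation, grid$n_azimuth)),
    class = "centre_surround_rf"
  )
}

#' @export
print.centre_surround_rf <- function(x, ...) {
  cat(sprintf(
    "<centre_surround_rf> %s eye at (%.1f, %.1f) deg, centre %g deg / surround %g deg\n",
    x$eye, x$centre_azimuth, x$centre_elevation, x$centre_radius,
    x$surround_radius
  ))
  invisible(x)
}

#' Default stimulus grid for the strike sensor
#'
#' A finer, narrower grid than the saccade retina: the strike system operates
#' near the midline.
#'
#' @param n Units per axis.
#' @param extent Half-width in degrees.
#' @return A [retinal_grid()].
#' @export
strike_grid <- function(n = 41, extent = 35) retinal_grid(n, n, extent)

#' Monocular drive
#'
#' Inner product of a processed frame with the receptive-field window.
#'
#' @param frame An `n_elevation x n_azimuth` matrix of rectified drive.
#' @param rf A [centre_surround_rf()] on the same grid.
#' @return Scalar drive.
#' @export
monocular_drive <- function(frame, rf) {
  stopifnot(inherits(rf, "centre_surround_rf"), is.matrix(frame))
  if (!all(dim(frame) == dim(rf$window))) {
    stop("frame shape does not match the receptive field's grid")
  }
  sum(frame * rf$window)
}

#' Binocular response
#'
#' Sums the monocular drives, half-wave thresholds, and raises to the
#' expansive power: `max(left + right - threshold, 0)^exponent`. With the
#' threshold at the peak monocular drive, a stimulus visible in only one eye
#' produces no response; with threshold 0, doubling both drives multiplies the
#' response by `2^exponent`.
#'
#' @param left_drive,right_drive Scalar monocular drives.
#' @param sensor A [strike_sensor()].
#' @return Scalar activity.
#' @export
binocular_response <- function(left_drive, right_drive, sensor) {
  stopifnot(inherits(sensor, "strike_sensor"),
            is.finite(left_drive), is.finite(right_drive))
  max(left_drive + right_drive - sensor$threshold, 0)^sensor$exponent
}

#' Construct a strike sensor
#'
#' Paired centre/surround receptive fields with nasal offsets chosen so the two
#' lines of sight intersect `preferred_distance` ahead of the head, an
#' expansive output nonlinearity, and a threshold/gain pair calibrated at
#' construction: the threshold is set to `threshold_factor` times the peak
#' monocular drive produced by the preferred stimulus (a disc of the centre's
#' angular size sweeping through the RF at the preferred distance), which
#' silences purely monocular stimulation; the gain is set so the preferred
#' stimulus peaks at `peak_probability` strike probability per frame.
#'
#' @param grid Stimulus grid; see [strike_grid()].
#' @param preferred_distance Distance (cm) at which the monocular lines of
#'   sight cross.
#' @param interocular Interocular distance in cm.
#' @param centre_radius,surround_radius RF radii in degrees (a 5 degree centre
#'   radius makes the preferred stimulus diameter about 10 degrees).
#' @param exponent Expansive power `p` (> 1).
#' @param threshold,gain Override the calibrated values.
#' @param threshold_factor Safety factor on the calibrated threshold.
#' @param peak_probability Target per-frame strike probability at the preferred
#'   stimulus peak.
#' @param preproc The [monocular_preproc()] used for calibration (and,
#'   conventionally, at run time).
#' @return An object of class `strike_sensor`.
#' @export
strike_sensor <- function(grid = strike_grid(), preferred_distance = 2.5,
                          interocular = 1, centre_radius = 5,
                          surround_radius = 10, exponent = 5,
                          threshold = NULL, gain = NULL,
                          threshold_factor = 1.2, peak_probability = 0.05,
                          preproc = monocular_preproc()) {
  stopifnot(exponent > 1, preferred_distance > 0, interocular > 0)
  offset <- .rad2deg(atan2(0.5 * interocular, preferred_distance))
  left_rf <- centre_surround_rf("left", -offset, 0, centre_radius,
                                surround_radius, grid = grid)
  right_rf <- centre_surround_rf("right", offset, 0, centre_radius,
                                 surround_radius, grid = grid)
  sensor <- structure(
    list(left_rf = left_rf, right_rf = right_rf, exponent = exponent,
         threshold = 0, gain = 1, grid = grid,
         preferred_distance = preferred_distance, interocular = interocular,
         preproc = preproc),
    class = "strike_sensor"
  )
  needs_threshold <- is.null(threshold)
  needs_gain <- is.null(gain)
  if (needs_threshold || needs_gain) {
    stim <- build_stimulus("moving_disc", distance = preferred_distance,
                           diameter = sphere_diameter_for_subtense(
                             preferred_distance, 2 * centre_radius),
                           grid = grid, interocular = interocular)
    drives <- .stimulus_drives(stim, sensor, preproc)
    mono_peak <- max(drives$left, drives$right, 0)
    if (needs_threshold) {
      sensor$threshold <- threshold_factor * mono_peak
    } else {
      sensor$threshold <- threshold
    }
    act <- pmax(drives$left + drives$right - sensor$threshold, 0)^exponent
    peak <- max(act)
    sensor$gain <- if (needs_gain) {
      if (peak > 0) peak_probability / peak else 0
    } else {
      gain
    }
  } else {
    sensor$threshold <- threshold
    sensor$gain <- gain
  }
  stopifnot(sensor$threshold >= 0, sensor$gain >= 0)
  sensor
}

#' @export
print.strike_sensor <- function(x, ...) {
  cat(sprintf(
    "<strike_sensor> centres at +/-%.1f deg (cross %.2g cm ahead), centre %g deg, p = %g, threshold %.3g, gain %.3g\n",
    abs(x$right_rf$centre_azimuth), x$preferred_distance,
    x$left_rf$centre_radius * 2, x$exponent, x$threshold, x$gain
  ))
  invisible(x)
}

# Internal: per-frame monocular drives for a stimulus.
.stimulus_drives <- function(stimulus, sensor, preproc) {
  dl <- preprocess(stimulus$left, preproc, stimulus$grid,
                   stimulus$frame_interval)
  dr <- preprocess(stimulus$right, preproc, stimulus$grid,
                   stimulus$frame_interval)
  n <- dim(dl)[3]
  left <- vapply(seq_len(n),
                 function(t) monocular_drive(dl[, , t], sensor$left_rf),
                 numeric(1))
  right <- vapply(seq_len(n),
                  function(t) monocular_drive(dr[, , t], sensor$right_rf),
                  numeric(1))
  list(left = left, right = right)
}

#' Deterministic activity trace of a trial
#'
#' Preprocesses both eyes, computes the per-frame monocular drives and applies
#' the binocular threshold-power nonlinearity.
#'
#' @param stimulus A [build_stimulus()] result.
#' @param sensor A [strike_sensor()].
#' @param preproc A [monocular_preproc()]; defaults to the sensor's.
#' @return Numeric per-frame activity vector.
#' @export
trial_activity <- function(stimulus, sensor, preproc = sensor$preproc) {
  stopifnot(inherits(stimulus, "dichoptic_stimulus"),
            inherits(sensor, "strike_sensor"))
  drives <- .stimulus_drives(stimulus, sensor, preproc)
  pmax(drives$left + drives$right - sensor$threshold, 0)^sensor$exponent
}

#' Sample strikes from an activity trace
#'
#' Per frame, a strike is a Bernoulli draw with probability
#' `min(gain * activity, 1)`; the expected count is `gain * sum(activity)`
#' whenever no frame is clipped. Uses R's global random number generator.
#'
#' @param activity Numeric per-frame activity.
#' @param gain Probability per unit activity per frame.
#' @return Integer strike count.
#' @export
sample_strikes <- function(activity, gain) {
  stopifnot(all(activity >= 0), gain >= 0)
  p <- pmin(gain * activity, 1)
  sum(stats::rbinom(length(p), 1, p))
}

#' Run one stochastic trial
#'
#' @inheritParams trial_activity
#' @return A list with `mean_activity`, `strike_count`, `n_frames` and the
#'   per-frame `activity` trace.
#' @export
run_trial <- function(stimulus, sensor, preproc = sensor$preproc) {
  act <- trial_activity(stimulus, sensor, preproc)
  list(mean_activity = mean(act),
       strike_count = sample_strikes(act, sensor$gain),
       n_frames = length(act),
       activity = act)
}

#' Build a dichoptic stimulus
#'
#' Three stimulus families used in the strike simulations:
#' \describe{
#'   \item{`moving_disc`}{A sphere of `diameter` at `distance`, sweeping in
#'     azimuth at constant angular speed through the midline.}
#'   \item{`ghost_pair`}{Two identical distant spheres placed on the monocular
#'     lines of sight of a virtual near sphere, so that each eye locally sees
#'     the same image as for the near sphere, plus a second image.}
#'   \item{`vertical_disparity`}{The moving disc with a pure vertical dichoptic
#'     offset (`+offset/2` elevation in the left eye, `-offset/2` in the
#'     right), geometrically impossible for a real object.}
#' }
#'
#' @param kind Stimulus kind.
#' @param distance Disc distance from the head origin in cm (for
#'   `ghost_pair`, the virtual near object's distance).
#' @param diameter Disc diameter in cm; default subtends 10 degrees at
#'   `distance`.
#' @param far_distance `ghost_pair` only: distance of the two real spheres
#'   from their matching eyes, in cm; must exceed each eye's distance to the
#'   virtual object.
#' @param offset `vertical_disparity` only: total vertical dichoptic offset in
#'   degrees.
#' @param azimuth_range Sweep range in degrees.
#' @param speed Sweep speed in degrees per second.
#' @param frame_interval Frame interval in seconds.
#' @param elevation Sweep elevation in degrees.
#' @param grid Stimulus grid.
#' @param interocular Interocular distance in cm.
#' @return An object of class `dichoptic_stimulus`: left/right frame arrays
#'   (`n_elevation x n_azimuth x n_frames`), the grid and the frame interval.
#' @export
build_stimulus <- function(kind = c("moving_disc", "ghost_pair",
                                    "vertical_disparity"),
                           distance = 2.5, diameter = NULL,
                           far_distance = 5, offset = 0,
                           azimuth_range = c(-25, 25), speed = 50,
                           frame_interval = 0.01, elevation = 0,
                           grid = strike_grid(), interocular = 1) {
  kind <- match.arg(kind)
  stopifnot(distance > 0, speed > 0, frame_interval > 0,
            azimuth_range[2] > azimuth_range[1])
  if (is.null(diameter)) diameter <- sphere_diameter_for_subtense(distance, 10)
  stopifnot(diameter > 0, distance > diameter / 2)
  pose <- head_pose(interocular = interocular)
  step <- speed * frame_interval
  azimuths <- seq(azimuth_range[1], azimuth_range[2], by = step)
  n_frames <- length(azimuths)
  if (n_frames < 2) stop("sweep too short for the given speed and range")
  u <- .grid_unit_vectors(grid)
  left <- array(0, c(grid$n_elevation, grid$n_azimuth, n_frames))
  right <- array(0, c(grid$n_elevation, grid$n_azimuth, n_frames))
  for (t in seq_len(n_frames)) {
    frame_scenes <- .stimulus_frame_scenes(kind, azimuths[t], elevation,
                                           distance, diameter, far_distance,
                                           offset, pose)
    left[, , t] <- .render_values(frame_scenes$left, pose, "left", grid, u)
    right[, , t] <- .render_values(frame_scenes$right, pose, "right", grid, u)
  }
  structure(
    list(left = left, right = right, grid = grid,
         frame_interval = frame_interval, kind = kind,
         params = list(distance = distance, diameter = diameter,
                       far_distance = far_distance, offset = offset,
                       azimuth_range = azimuth_range, speed = speed,
                       elevation = elevation, interocular = interocular)),
    class = "dichoptic_stimulus"
  )
}

#' @export
print.dichoptic_stimulus <- function(x, ...) {
  cat(sprintf("<dichoptic_stimulus> %s, %d frames at %g ms, %d x %d units\n",
              x$kind, dim(x$left)[3], 1000 * x$frame_interval,
              x$grid$n_elevation, x$grid$n_azimuth))
  invisible(x)
}

# Internal: per-eye scene for one stimulus frame.
.stimulus_frame_scenes <- function(kind, azimuth, elevation, distance,
                                   diameter, far_distance, offset, pose) {
  if (kind == "moving_disc") {
    s <- scene(azimuth, elevation, distance, diameter)
    return(list(left = s, right = s))
  }
  if (kind == "vertical_disparity") {
    return(list(
      left = scene(azimuth, elevation + offset / 2, distance, diameter),
      right = scene(azimuth, elevation - offset / 2, distance, diameter)
    ))
  }
  # ghost_pair: place one sphere along each eye's line of sight to the virtual
  # near object, at far_distance from that eye, with diameter scaled to keep
  # the same angular subtense from the matching eye.
  near <- direction_to_point(head_direction(azimuth, elevation, distance))
  spheres <- lapply(c("left", "right"), function(eye) {
    nodal <- eye_nodal_point(pose, eye)
    v <- near - nodal
    d_eye <- sqrt(sum(v^2))
    if (far_distance <= d_eye) {
      stop("ghost geometry unrealizable: far_distance must exceed the ",
           "eye-to-object distance")
    }
    p <- nodal + v / d_eye * far_distance
    dir <- world_to_head(head_pose(interocular = pose$interocular), p)
    list(azimuth = dir$azimuth, elevation = dir$elevation,
         distance = dir$distance,
         diameter = diameter * far_distance / d_eye)
  })
  s <- scene(
    azimuth = vapply(spheres, `[[`, numeric(1), "azimuth"),
    elevation = vapply(spheres, `[[`, numeric(1), "elevation"),
    distance = vapply(spheres, `[[`, numeric(1), "distance"),
    diameter = vapply(spheres, `[[`, numeric(1), "diameter")
  )
  list(left = s, right = s)
}
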