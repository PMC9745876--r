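# Retinal grids, synthetic scenes of spherical targets, rendering and labels.

#' Lat-long retinal grid
#'
#' A rectangular grid of visual directions, equally spaced in azimuth-longitude
#' and elevation-latitude. The default matches the model retina: 51 x 51 units
#' from -70 to +70 degrees, a spacing of 2.8 degrees between units.
#'
#' Grid cells are stored column-major with elevation varying fastest, i.e. cell
#' `k` has elevation index `(k - 1) %% n_elevation + 1` and azimuth index
#' `(k - 1) %/% n_elevation + 1`. All images and network layers use this order.
#'
#' @param n_azimuth,n_elevation Number of units along each axis.
#' @param extent Half-width of the grid in degrees.
#' @return An object of class `retinal_grid`.
#' @export
retinal_grid <- function(n_azimuth = 51, n_elevation = 51, extent = 70) {
  stopifnot(n_azimuth >= 2, n_elevation >= 2, extent > 0, extent <= 90)
  structure(
    list(
      n_azimuth = as.integer(n_azimuth),
      n_elevation = as.integer(n_elevation),
      extent = extent,
      azimuths = seq(-extent, extent, length.out = n_azimuth),
      elevations = seq(-extent, extent, length.out = n_elevation)
    ),
    class = "retinal_grid"
  )
}

#' @export
print.retinal_grid <- function(x, ...) {
  cat(sprintf(
    "<retinal_grid> %d x %d units, +/-%g deg, spacing %.3g deg (azimuth) x %.3g deg (elevation)\n",
    x$n_azimuth, x$n_elevation, x$extent,
    diff(x$azimuths[1:2]), diff(x$elevations[1:2])
  ))
  invisible(x)
}

#' Grid cell directions
#'
#' Azimuth and elevation of every grid cell, in the package's flattening order
#' (elevation fastest).
#'
#' @param grid A [retinal_grid()].
#' @return A data frame with columns `azimuth` and `elevation` (degrees), one
#'   row per cell.
#' @export
grid_directions <- function(grid) {
  stopifnot(inherits(grid, "retinal_grid"))
  expand.grid(elevation = grid$elevations, azimuth = grid$azimuths,
              KEEP.OUT.ATTRS = FALSE)[, c("azimuth", "elevation")]
}

# Internal: n_cells x 3 matrix of unit direction vectors, one row per cell,
# in flattening order.
.grid_unit_vectors <- function(grid) {
  d <- grid_directions(grid)
  a <- .deg2rad(d$azimuth)
  k <- .deg2rad(d$elevation)
  cbind(cos(k) * sin(a), sin(k), cos(k) * cos(a))
}

# Internal: nearest grid cell to (azimuth, elevation) by Euclidean distance in
# the (azimuth, elevation) chart; returns list(az_index, el_index, index).
.nearest_grid_cell <- function(grid, azimuth, elevation) {
  ia <- which.min(abs(grid$azimuths - azimuth))
  ie <- which.min(abs(grid$elevations - elevation))
  list(az_index = ia, el_index = ie,
       index = (ia - 1L) * grid$n_elevation + ie)
}

#' Sphere diameter for a given angular subtense
#'
#' Inverts the angular-subtense convention used throughout:
#' `subtense = 2 * asin(radius / distance)`, the exact silhouette angle of a
#' sphere seen from a point. A sphere 8 cm away subtending 15 degrees has
#' diameter 2.1 cm (to one decimal).
#'
#' @param distance Distance from the viewing point in cm; positive.
#' @param subtense Angular subtense in degrees, in `[0, 180)`.
#' @return Diameter in cm.
#' @export
sphere_diameter_for_subtense <- function(distance, subtense) {
  stopifnot(all(distance > 0), all(subtense >= 0), all(subtense < 180))
  2 * distance * sin(.deg2rad(subtense) / 2)
}

#' Angular subtense of a sphere
#'
#' @param diameter Sphere diameter in cm.
#' @param distance Distance from the viewing point in cm; must exceed the
#'   radius.
#' @return Subtense in degrees.
#' @export
sphere_subtense <- function(diameter, distance) {
  stopifnot(all(diameter > 0), all(distance > diameter / 2))
  2 * .rad2deg(asin(diameter / 2 / distance))
}

#' Construct a scene of spherical targets
#'
#' A scene is a data frame with one sphere per row: headcentric azimuth and
#' elevation (degrees), distance from the head origin (cm) and diameter (cm).
#' Scenes live in the world frame with the default (identity) head pose at the
#' origin; spheres are placed along the stated directions.
#'
#' @param azimuth,elevation,distance,diameter Equal-length numeric vectors
#'   (recycled by `data.frame`); may all be empty for an empty scene.
#' @return An object of class `scene` (also a data frame).
#' @export
scene <- function(azimuth = numeric(), elevation = numeric(),
                  distance = numeric(), diameter = numeric()) {
  s <- data.frame(azimuth = azimuth, elevation = elevation,
                  distance = distance, diameter = diameter)
  if (nrow(s) > 0) {
    stopifnot(all(is.finite(as.matrix(s))), all(s$diameter > 0),
              all(s$distance > s$diameter / 2))
  }
  class(s) <- c("scene", "data.frame")
  s
}

#' Sample a random training scene
#'
#' Draws spherical targets with azimuths and elevations independent normal
#' (mean 0, s.d. `direction_sd`), distances uniform on `distance_range`, and
#' diameters scaled so every sphere subtends `subtense` degrees at the origin.
#' Defaults follow the training protocol: four spheres, s.d. 45 degrees,
#' distances 1-11 cm, 10 degree subtense.
#'
#' Uses R's global random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param n_objects Number of spheres (0 gives an empty scene).
#' @param direction_sd S.d. of azimuth and elevation in degrees.
#' @param distance_range Length-2 numeric range of distances in cm.
#' @param subtense Angular subtense of every sphere at the origin, degrees.
#' @return A [scene()].
#' @export
sample_training_scene <- function(n_objects = 4, direction_sd = 45,
                                  distance_range = c(1, 11), subtense = 10) {
  stopifnot(n_objects >= 0, direction_sd > 0,
            length(distance_range) == 2, distance_range[1] > 0,
            distance_range[2] >= distance_range[1],
            subtense > 0, subtense < 180)
  n <- as.integer(n_objects)
  if (n == 0) return(scene())
  d <- stats::runif(n, distance_range[1], distance_range[2])
  scene(
    azimuth = stats::rnorm(n, 0, direction_sd),
    elevation = stats::rnorm(n, 0, direction_sd),
    distance = d,
    diameter = sphere_diameter_for_subtense(d, subtense)
  )
}

# Internal: world coordinates of sphere centres, n x 3.
.scene_points <- function(scene) {
  if (nrow(scene) == 0) return(matrix(numeric(), 0, 3))
  a <- .deg2rad(scene$azimuth)
  k <- .deg2rad(scene$elevation)
  scene$distance * cbind(cos(k) * sin(a), sin(k), cos(k) * cos(a))
}

#' Render a scene onto one retina
#'
#' Projects every sphere onto the eye and activates (value 1) each grid unit
#' whose direction lies within the sphere's angular radius as seen from that
#' eye's nodal point; all other units are 0. Rendering is binary by unit-centre
#' inclusion, spheres are unioned (no occlusion) and background is 0.
#'
#' @param scene A [scene()].
#' @param pose A [head_pose()].
#' @param eye `"left"` or `"right"`.
#' @param grid A [retinal_grid()].
#' @return An object of class `retinal_image`: list with `eye`, `values`
#'   (an `n_elevation` x `n_azimuth` matrix) and `grid`.
#' @export
render_scene <- function(scene, pose = head_pose(), eye = c("left", "right"),
                         grid = retinal_grid()) {
  stopifnot(inherits(scene, "scene"), inherits(pose, "head_pose"),
            inherits(grid, "retinal_grid"))
  eye <- match.arg(eye)
  u <- .grid_unit_vectors(grid)
  vals <- .render_values(scene, pose, eye, grid, u)
  retinal_image(eye, matrix(vals, grid$n_elevation, grid$n_azimuth), grid)
}

# Internal rendering core; `u` is the precomputed unit-vector matrix so batch
# renderers can amortize it. Returns a flat 0/1 vector in flattening order.
.render_values <- function(scene, pose, eye, grid, u) {
  n_cells <- grid$n_azimuth * grid$n_elevation
  active <- logical(n_cells)
  if (nrow(scene) > 0) {
    nodal <- eye_nodal_point(pose, eye)
    pts <- .scene_points(scene)
    rot_t <- t(pose$rotation)
    for (i in seq_len(nrow(scene))) {
      v <- as.numeric(rot_t %*% (pts[i, ] - nodal))
      d <- sqrt(sum(v^2))
      r <- scene$diameter[i] / 2
      if (d <= r) {        # eye inside the sphere: fills the whole field
        active[] <- TRUE
        next
      }
      ang_r <- asin(r / d)
      active <- active | (u %*% (v / d) >= cos(ang_r))
    }
  }
  as.numeric(active)
}

#' Construct a retinal image
#'
#' @param eye `"left"` or `"right"`.
#' @param values An `n_elevation` x `n_azimuth` numeric matrix of activations.
#' @param grid The [retinal_grid()] the image is sampled on.
#' @return An object of class `retinal_image`.
#' @export
retinal_image <- function(eye = c("left", "right"), values,
                          grid = retinal_grid()) {
  eye <- match.arg(eye)
  stopifnot(is.matrix(values),
            nrow(values) == grid$n_elevation, ncol(values) == grid$n_azimuth)
  structure(list(eye = eye, values = values, grid = grid),
            class = "retinal_image")
}

#' @export
print.retinal_image <- function(x, ...) {
  cat(sprintf("<retinal_image> %s eye, %d x %d units, %d active (>0)\n",
              x$eye, x$grid$n_elevation, x$grid$n_azimuth, sum(x$values > 0)))
  invisible(x)
}

#' Add clipped Gaussian noise to a retinal image
#'
#' Adds independent zero-mean Gaussian noise of s.d. `sigma` to every unit and
#' clips the result at zero (activations cannot be negative). `sigma = 0`
#' returns the image unchanged. Uses R's global random number generator.
#'
#' @param image A [retinal_image()].
#' @param sigma Noise s.d. in activation units (target amplitude is 1).
#' @return A `retinal_image` of the same shape.
#' @export
add_noise <- function(image, sigma = 0.1) {
  stopifnot(inherits(image, "retinal_image"), is.finite(sigma), sigma >= 0)
  if (sigma == 0) return(image)
  v <- pmax(image$values + stats::rnorm(length(image$values), 0, sigma), 0)
  retinal_image(image$eye, matrix(v, nrow(image$values)), image$grid)
}

#' Label a scene with its correct saccade target
#'
#' Among spheres whose centre is visible (projects within the grid extent of at
#' least one eye), picks the one nearest the head and returns the output-grid
#' unit closest to its headcentric direction. If no sphere is visible, returns
#' the unit encoding (0, 0) with `is_no_action` set; that is also set whenever
#' the winning unit is the (0, 0) unit.
#'
#' @param scene A [scene()].
#' @param grid The output [retinal_grid()].
#' @param pose A [head_pose()].
#' @return A list of class `scene_label` with `az_index`, `el_index`, `index`
#'   (flattened), `azimuth`, `elevation` and `is_no_action`.
#' @export
label_scene <- function(scene, grid = retinal_grid(), pose = head_pose()) {
  stopifnot(inherits(scene, "scene"), inherits(grid, "retinal_grid"),
            inherits(pose, "head_pose"))
  target <- .nearest_visible_sphere(scene, grid, pose)
  if (is.null(target)) {
    cell <- .nearest_grid_cell(grid, 0, 0)
    dir_az <- grid$azimuths[cell$az_index]
    dir_el <- grid$elevations[cell$el_index]
  } else {
    cell <- .nearest_grid_cell(grid, target$azimuth, target$elevation)
    dir_az <- grid$azimuths[cell$az_index]
    dir_el <- grid$elevations[cell$el_index]
  }
  zero <- .nearest_grid_cell(grid, 0, 0)
  structure(
    list(az_index = cell$az_index, el_index = cell$el_index,
         index = cell$index, azimuth = dir_az, elevation = dir_el,
         is_no_action = cell$index == zero$index),
    class = "scene_label"
  )
}

# Internal: head_direction of the nearest sphere whose centre projects within
# the grid extent of at least one eye, or NULL if none.
.nearest_visible_sphere <- function(scene, grid, pose) {
  if (nrow(scene) == 0) return(NULL)
  pts <- .scene_points(scene)
  visible <- logical(nrow(scene))
  for (i in seq_len(nrow(scene))) {
    for (eye in c("left", "right")) {
      p <- project_to_retina(pose, eye, pts[i, ])
      if (abs(p$azimuth) <= grid$extent && abs(p$elevation) <= grid$extent) {
        visible[i] <- TRUE
        break
      }
    }
  }
  if (!any(visible)) return(NULL)
  dist_head <- sqrt(rowSums(sweep(pts, 2, pose$position)^2))
  i <- which(visible)[which.min(dist_head[visible])]
  world_to_head(pose, pts[i, ])
}

#' Write / read a scene table
#'
#' Scene collections serialize to plain CSV with one sphere per row and a
#' `scene_id` column.
#'
#' @param scenes A list of [scene()] objects.
#' @param file Path to a CSV file.
#' @return `write_scene_table` returns `file` invisibly; `read_scene_table`
#'   returns a list of scenes.
#' @export
write_scene_table <- function(scenes, file) {
  stopifnot(is.list(scenes), all(vapply(scenes, inherits, TRUE, "scene")))
  rows <- lapply(seq_along(scenes), function(i) {
    s <- as.data.frame(scenes[[i]])
    if (nrow(s) == 0) return(NULL)
    cbind(scene_id = i, s)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(scene_id = integer(), azimuth = numeric(),
                      elevation = numeric(), distance = numeric(),
                      diameter = numeric())
  }
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_scene_table
#' @param n_scenes Number of scenes to reconstruct; defaults to the largest
#'   `scene_id` in the file (empty trailing scenes are not recoverable from
#'   CSV, so state it explicitly if they matter).
#' @export
read_scene_table <- function(file, n_scenes = NULL) {
  tab <- utils::read.csv(file)
  need <- c("scene_id", "azimuth", "elevation", "distance", "diameter")
  if (!all(need %in% names(tab))) stop("malformed scene table: ", file)
  if (is.null(n_scenes)) n_scenes <- if (nrow(tab)) max(tab$scene_id) else 0
  lapply(seq_len(n_scenes), function(i) {
    s <- tab[tab$scene_id == i, , drop = FALSE]
    scene(s$azimuth, s$elevation, s$distance, s$diameter)
  })
}
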