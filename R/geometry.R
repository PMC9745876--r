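# Binocular viewing geometry in Fick coordinates.
#
# Conventions: right-handed world frame with Z pointing out in front of the
# animal and Y vertically upwards; positive azimuth is an anti-clockwise
# rotation about Y, so azimuth increases towards +X (the left eye's side).
# Angles are stored and reported in degrees; trigonometry is done in radians.

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Fick rotation matrix
#'
#' Builds the 3x3 rotation matrix for an azimuth-longitude / elevation-latitude
#' pair in Fick coordinates: the elevation rotation (about X) is applied first,
#' then the azimuth rotation (about Y). Applied to the forward axis
#' `Z = c(0, 0, 1)` it gives the unit vector
#' `c(cos(el) * sin(az), sin(el), cos(el) * cos(az))`.
#'
#' @param azimuth Azimuth-longitude in degrees.
#' @param elevation Elevation-latitude in degrees.
#' @return A 3x3 orthonormal rotation matrix with determinant +1.
#' @examples
#' fick_rotation(0, 0)            # identity
#' fick_rotation(90, 0) %*% c(0, 0, 1)  # gaze swings to +X
#' @export
fick_rotation <- function(azimuth, elevation) {
  stopifnot(is.finite(azimuth), is.finite(elevation))
  a <- .deg2rad(azimuth)
  k <- .deg2rad(elevation)
  ry <- matrix(c(
    cos(a), 0, sin(a),
    0, 1, 0,
    -sin(a), 0, cos(a)
  ), nrow = 3, byrow = TRUE)
  rx <- matrix(c(
    1, 0, 0,
    0, cos(k), sin(k),
    0, -sin(k), cos(k)
  ), nrow = 3, byrow = TRUE)
  ry %*% rx
}

# Inverse of fick_rotation: recover (azimuth, elevation) in degrees from a
# Fick rotation matrix. Elevation is restricted to [-90, 90] by the latitude
# convention; azimuth uses the two-argument arctangent for correct quadrants.
.fick_angles <- function(m) {
  elevation <- asin(max(-1, min(1, m[2, 3])))
  azimuth <- atan2(m[1, 3], m[3, 3])
  c(azimuth = .rad2deg(azimuth), elevation = .rad2deg(elevation))
}

#' Head pose
#'
#' A head pose: position of the midpoint between the eyes, Fick azimuth and
#' elevation of the head relative to the world axes, and the interocular
#' distance. The default pose is the one used throughout the simulations: head
#' at the origin, looking down +Z, eyes 1 cm apart.
#'
#' @param azimuth,elevation Head orientation in degrees (Fick coordinates).
#' @param position Numeric length-3 world position of the head in cm.
#' @param interocular Interocular distance in cm; must be positive.
#' @return An object of class `head_pose`.
#' @export
head_pose <- function(azimuth = 0, elevation = 0, position = c(0, 0, 0),
                      interocular = 1) {
  stopifnot(
    is.numeric(position), length(position) == 3, all(is.finite(position)),
    is.finite(azimuth), is.finite(elevation),
    is.finite(interocular), interocular > 0
  )
  structure(
    list(
      azimuth = azimuth,
      elevation = elevation,
      position = as.numeric(position),
      interocular = interocular,
      rotation = fick_rotation(azimuth, elevation)
    ),
    class = "head_pose"
  )
}

#' @export
print.head_pose <- function(x, ...) {
  cat(sprintf(
    "<head_pose> azimuth %.2f deg, elevation %.2f deg, position (%g, %g, %g) cm, I = %g cm\n",
    x$azimuth, x$elevation, x$position[1], x$position[2], x$position[3],
    x$interocular
  ))
  invisible(x)
}

#' Head-centred direction
#'
#' A direction and distance relative to the head: Fick azimuth-longitude,
#' elevation-latitude (degrees) and Euclidean distance (cm).
#'
#' @param azimuth,elevation Direction in degrees.
#' @param distance Distance in cm; must be positive.
#' @return An object of class `head_direction`.
#' @export
head_direction <- function(azimuth, elevation, distance) {
  stopifnot(is.finite(azimuth), is.finite(elevation),
            is.finite(distance), distance > 0)
  structure(
    list(azimuth = azimuth, elevation = elevation, distance = distance),
    class = "head_direction"
  )
}

#' @export
print.head_direction <- function(x, ...) {
  cat(sprintf("<head_direction> azimuth %.2f deg, elevation %.2f deg, distance %g cm\n",
              x$azimuth, x$elevation, x$distance))
  invisible(x)
}

#' Convert a head-centred direction to a point
#'
#' Reconstructs Cartesian coordinates from a `head_direction`:
#' `distance * c(cos(el) sin(az), sin(el), cos(el) cos(az))`, expressed in the
#' frame of `pose` and then (by default) mapped to world coordinates.
#'
#' @param direction A [head_direction()].
#' @param pose A [head_pose()]; defaults to the identity pose at the origin.
#' @return Numeric length-3 world coordinates in cm.
#' @export
direction_to_point <- function(direction, pose = head_pose()) {
  stopifnot(inherits(direction, "head_direction"), inherits(pose, "head_pose"))
  a <- .deg2rad(direction$azimuth)
  k <- .deg2rad(direction$elevation)
  v <- direction$distance * c(cos(k) * sin(a), sin(k), cos(k) * cos(a))
  as.numeric(pose$position + pose$rotation %*% v)
}

#' Eye nodal point
#'
#' World coordinates of an eye's nodal point: the head position displaced by
#' half the interocular distance along the head's X axis, `+` for the left eye
#' and `-` for the right.
#'
#' @param pose A [head_pose()].
#' @param eye `"left"` or `"right"`.
#' @return Numeric length-3 world coordinates in cm.
#' @export
eye_nodal_point <- function(pose, eye = c("left", "right")) {
  stopifnot(inherits(pose, "head_pose"))
  eye <- match.arg(eye)
  s <- if (eye == "left") 1 else -1
  as.numeric(pose$position +
               s * 0.5 * pose$interocular * pose$rotation %*% c(1, 0, 0))
}

# Internal: world point -> (azimuth, elevation, distance) about an arbitrary
# centre, using the frame of `rotation`.
.point_to_fick <- function(point, centre, rotation) {
  v <- as.numeric(t(rotation) %*% (as.numeric(point) - as.numeric(centre)))
  d <- sqrt(sum(v^2))
  if (d == 0) {
    stop("point coincides with the projection centre; direction is undefined")
  }
  c(
    azimuth = .rad2deg(atan2(v[1], v[3])),
    elevation = .rad2deg(asin(max(-1, min(1, v[2] / d)))),
    distance = d
  )
}

#' World point to head-centred direction
#'
#' Inverse-transforms a world point into the head frame and extracts its Fick
#' azimuth-longitude, elevation-latitude and distance.
#'
#' @param pose A [head_pose()].
#' @param point Numeric length-3 world coordinates in cm.
#' @return A [head_direction()].
#' @export
world_to_head <- function(pose, point) {
  stopifnot(inherits(pose, "head_pose"),
            is.numeric(point), length(point) == 3, all(is.finite(point)))
  f <- .point_to_fick(point, pose$position, pose$rotation)
  head_direction(f[["azimuth"]], f[["elevation"]], f[["distance"]])
}

#' Project a world point onto one retina
#'
#' The eyes are fixed on the head and share its rotation matrix, so projection
#' is the head-frame transform taken about the eye's nodal point instead of the
#' head centre.
#'
#' @param pose A [head_pose()].
#' @param eye `"left"` or `"right"`.
#' @param point Numeric length-3 world coordinates in cm.
#' @return An object of class `retinal_direction` with fields `eye`, `azimuth`,
#'   `elevation` (degrees) and `distance` (cm, from the nodal point).
#' @examples
#' # A target 4 cm away at azimuth -15 deg projects to about -22 deg in the
#' # left eye and -8 deg in the right (I = 1 cm):
#' p <- direction_to_point(head_direction(-15, 0, 4))
#' project_to_retina(head_pose(), "left", p)
#' project_to_retina(head_pose(), "right", p)
#' @export
project_to_retina <- function(pose, eye = c("left", "right"), point) {
  stopifnot(inherits(pose, "head_pose"),
            is.numeric(point), length(point) == 3, all(is.finite(point)))
  eye <- match.arg(eye)
  f <- .point_to_fick(point, eye_nodal_point(pose, eye), pose$rotation)
  structure(
    list(eye = eye, azimuth = f[["azimuth"]], elevation = f[["elevation"]],
         distance = f[["distance"]]),
    class = "retinal_direction"
  )
}

#' @export
print.retinal_direction <- function(x, ...) {
  cat(sprintf("<retinal_direction> %s eye: azimuth %.2f deg, elevation %.2f deg, distance %g cm\n",
              x$eye, x$azimuth, x$elevation, x$distance))
  invisible(x)
}

#' Binocular view of a point
#'
#' Projects a point into both eyes and reports the two monocular azimuths
#' together with the derived cyclopean (headcentric) azimuth
#' `(alpha_R + alpha_L) / 2` and the disparity `alpha_R - alpha_L`, which is
#' positive within the binocular overlap and larger for nearer points.
#'
#' @inheritParams project_to_retina
#' @return A list with components `left`, `right` (both `retinal_direction`),
#'   `headcentric_azimuth` and `disparity` (degrees).
#' @export
binocular_view <- function(pose, point) {
  left <- project_to_retina(pose, "left", point)
  right <- project_to_retina(pose, "right", point)
  list(
    left = left,
    right = right,
    headcentric_azimuth = (right$azimuth + left$azimuth) / 2,
    disparity = right$azimuth - left$azimuth
  )
}

#' Refixate on a target
#'
#' Turns the head to fixate a target: the new pose's rotation matrix is the old
#' one postmultiplied by the Fick matrix of the target's head-centred azimuth
#' and elevation. The head position does not change. After refixation the
#' target lies on the gaze vector (azimuth = elevation = 0).
#'
#' @param pose A [head_pose()].
#' @param target A [head_direction()] giving the target as seen from `pose`.
#' @return The new `head_pose`.
#' @export
refixate <- function(pose, target) {
  stopifnot(inherits(pose, "head_pose"), inherits(target, "head_direction"))
  m_new <- pose$rotation %*% fick_rotation(target$azimuth, target$elevation)
  ang <- .fick_angles(m_new)
  head_pose(ang[["azimuth"]], ang[["elevation"]], pose$position,
            pose$interocular)
}
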