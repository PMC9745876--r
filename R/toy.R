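# Didactic constructs: binocular units on a discrete ensemble of monocular
# inner products, and the sensor-lattice ambiguity demonstration.

#' Discrete ensemble of monocular inner products
#'
#' A small set of possible values of the monocular inner product `W . I`, each
#' equally probable. The default `{1, 2, 3}` is the classic reduced ensemble.
#'
#' @param values Non-empty numeric vector of inner-product values.
#' @return An object of class `discrete_ensemble`.
#' @export
discrete_ensemble <- function(values = c(1, 2, 3)) {
  stopifnot(length(values) >= 1, all(is.finite(values)))
  structure(list(values = as.numeric(values)), class = "discrete_ensemble")
}

#' Binocular unit
#'
#' Response forms to a pair of monocular inner products `(l, r)`:
#' \describe{
#'   \item{`linear`}{`l + r` — completely insensitive to correspondence.}
#'   \item{`energy`}{`(l + r)^2` — weak correspondence: matching pairs respond
#'     more on average.}
#'   \item{`thresholded_linear`}{`l + r`, with responses below `threshold` set
#'     to 0 — a threshold has a similar correspondence-inducing effect.}
#' }
#'
#' @param kind Unit kind.
#' @param threshold Threshold for `thresholded_linear` (default 4).
#' @return An object of class `binocular_unit`.
#' @export
binocular_unit <- function(kind = c("linear", "energy", "thresholded_linear"),
                           threshold = 4) {
  kind <- match.arg(kind)
  structure(list(kind = kind, threshold = threshold),
            class = "binocular_unit")
}

#' Unit response to a pair of monocular inner products
#'
#' @param unit A [binocular_unit()].
#' @param left,right Monocular inner-product values (vectorized).
#' @return Numeric response.
#' @export
unit_response <- function(unit, left, right) {
  stopifnot(inherits(unit, "binocular_unit"))
  s <- left + right
  switch(unit$kind,
    linear = s,
    energy = s^2,
    thresholded_linear = ifelse(s < unit$threshold, 0, s)
  )
}

#' Mean response over matched or non-matched pairs
#'
#' Exact enumeration mean of the unit's response, over the matched pairs
#' `(v, v)` or the unordered non-matching pairs `{v, w}`, `v != w`, of the
#' ensemble, all equally weighted. For the thresholded linear unit (threshold
#' 4) on the ensemble `{1, 2, 3}`, the non-matching mean is `mean(c(0, 4, 5))
#' = 3` and the matching mean is `mean(c(0, 4, 6)) = 10/3`.
#'
#' @param unit A [binocular_unit()].
#' @param ensemble A [discrete_ensemble()].
#' @param matched If `TRUE`, average over matched pairs; otherwise over
#'   unordered non-matching pairs.
#' @return Scalar mean response.
#' @export
mean_response <- function(unit, ensemble, matched) {
  stopifnot(inherits(unit, "binocular_unit"),
            inherits(ensemble, "discrete_ensemble"),
            is.logical(matched), length(matched) == 1)
  v <- ensemble$values
  if (matched) {
    return(mean(unit_response(unit, v, v)))
  }
  if (length(v) < 2) stop("non-matching pairs need at least 2 ensemble values")
  pairs <- utils::combn(seq_along(v), 2)
  mean(unit_response(unit, v[pairs[1, ]], v[pairs[2, ]]))
}

#' Sensor lattice
#'
#' The set of disparity sensors formed by pairing each of `n_left` monocular
#' locations in the left eye with each of `n_right` in the right; every
#' `(left, right)` location pair is one sensor.
#'
#' @param n_left,n_right Monocular location counts.
#' @return An object of class `sensor_lattice` with a data frame of sensors.
#' @export
sensor_lattice <- function(n_left = 4, n_right = 4) {
  stopifnot(n_left >= 1, n_right >= 1)
  sensors <- expand.grid(left = seq_len(n_left), right = seq_len(n_right),
                         KEEP.OUT.ATTRS = FALSE)
  structure(list(n_left = as.integer(n_left), n_right = as.integer(n_right),
                 sensors = sensors),
            class = "sensor_lattice")
}

#' Feed-forward sensor activations on the lattice
#'
#' Each object occupies one monocular location per eye and carries an identity.
#' A sensor is active iff some object image occupies its left location, some
#' object image occupies its right location, and the local-match predicate
#' accepts the pair: with `distinguishable = TRUE` the two images must come
#' from the same object; with `FALSE` any co-occupation counts (the images are
#' locally identical, so every pairing is a perfect local match). One object
#' activates exactly one sensor; two indistinguishable objects activate four
#' (the two true locations plus two ghosts); two distinguishable objects
#' activate only their two true sensors.
#'
#' @param lattice A [sensor_lattice()].
#' @param objects A data frame with columns `left` and `right` (monocular
#'   location indices), one row per object.
#' @param distinguishable Can the sensors tell the objects' images apart?
#' @return A data frame of active sensors with columns `left` and `right`.
#' @export
lattice_activations <- function(lattice, objects, distinguishable = FALSE) {
  stopifnot(inherits(lattice, "sensor_lattice"), is.data.frame(objects),
            all(c("left", "right") %in% names(objects)))
  if (nrow(objects) > 0) {
    stopifnot(all(objects$left >= 1), all(objects$left <= lattice$n_left),
              all(objects$right >= 1), all(objects$right <= lattice$n_right))
  }
  s <- lattice$sensors
  active <- vapply(seq_len(nrow(s)), function(i) {
    li <- which(objects$left == s$left[i])
    ri <- which(objects$right == s$right[i])
    if (length(li) == 0 || length(ri) == 0) return(FALSE)
    if (!distinguishable) return(TRUE)
    length(intersect(li, ri)) > 0
  }, logical(1))
  s[active, , drop = FALSE]
}
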