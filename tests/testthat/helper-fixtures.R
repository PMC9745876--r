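# Shared fixtures, built once per test run.
#
# The trained network uses the scaled-down preset (25 x 25 grids, 20 000
# scenes, 4 epochs, seed 1): minutes on one CPU, and large enough for the
# behavioural properties (fusion, near preference, weight structure).

.fixtures <- new.env(parent = emptyenv())

trained_test_network <- function() {
  if (is.null(.fixtures$net)) {
    .fixtures$net <- train_saccade_network(
      training_config(preset = "scaled_down", seed = 1)
    )
  }
  .fixtures$net
}

# The desk preset: full 51 x 51 grid geometry with a reduced training budget
# (20 000 scenes, 8 epochs; ~8 minutes). Used for the behavioural headline
# checks, which need direction resolved at the 2.8-degree grid spacing.
desk_test_network <- function() {
  if (is.null(.fixtures$desk_net)) {
    .fixtures$desk_net <- train_saccade_network(
      training_config(preset = "desk", seed = 1)
    )
  }
  .fixtures$desk_net
}

default_test_sensor <- function() {
  if (is.null(.fixtures$sensor)) {
    .fixtures$sensor <- strike_sensor()
  }
  .fixtures$sensor
}

# Mirror-symmetrize a network about the vertical midline: average the weights
# with their reflection (output azimuth flipped, input azimuth flipped, eyes
# swapped). The result treats left and right targets identically, isolating
# stimulus asymmetries from training idiosyncrasies.
symmetrize_network <- function(net) {
  g <- net$input_grid
  og <- net$output_grid
  n_cells <- g$n_azimuth * g$n_elevation
  flip <- function(grid) {
    idx <- matrix(seq_len(grid$n_azimuth * grid$n_elevation),
                  grid$n_elevation, grid$n_azimuth)
    as.vector(idx[, rev(seq_len(grid$n_azimuth))])
  }
  in_flip <- flip(g)
  # input permutation: flip azimuth within each eye, then swap eyes
  in_perm <- c(n_cells + in_flip, in_flip)
  out_perm <- flip(og)
  w2 <- net$weights[out_perm, in_perm]
  b2 <- net$biases[out_perm]
  net$weights <- (net$weights + w2) / 2
  net$biases <- (net$biases + b2) / 2
  net
}

# Independent per-unit rendering oracle: activates a grid unit iff the angle
# between the unit's direction and the sphere-centre direction, both taken at
# the eye's nodal point, is at most the sphere's angular radius seen from the
# eye. Plain loops, no shared code with render_scene's vectorized path.
render_oracle <- function(scene, pose, eye, grid) {
  vals <- matrix(0, grid$n_elevation, grid$n_azimuth)
  nodal <- eye_nodal_point(pose, eye)
  for (s in seq_len(nrow(scene))) {
    a <- scene$azimuth[s] * pi / 180
    k <- scene$elevation[s] * pi / 180
    p <- scene$distance[s] * c(cos(k) * sin(a), sin(k), cos(k) * cos(a))
    v <- as.numeric(t(pose$rotation) %*% (p - nodal))
    d <- sqrt(sum(v^2))
    ang_r <- asin(scene$diameter[s] / 2 / d)
    for (ia in seq_len(grid$n_azimuth)) {
      for (ie in seq_len(grid$n_elevation)) {
        aa <- grid$azimuths[ia] * pi / 180
        kk <- grid$elevations[ie] * pi / 180
        u <- c(cos(kk) * sin(aa), sin(kk), cos(kk) * cos(aa))
        if (acos(max(-1, min(1, sum(u * v / d)))) <= ang_r) {
          vals[ie, ia] <- 1
        }
      }
    }
  }
  vals
}
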