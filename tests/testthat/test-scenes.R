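test_that("the default retinal grid matches the model retina", {
  g <- retinal_grid()
  expect_equal(c(g$n_azimuth, g$n_elevation), c(51L, 51L))
  expect_equal(range(g$azimuths), c(-70, 70))
  expect_equal(diff(g$azimuths[1:2]), 2.8)
  expect_true(0 %in% g$azimuths)
})

test_that("sphere diameter inverts the subtense convention", {
  expect_equal(round(sphere_diameter_for_subtense(8, 15), 1), 2.1)
  expect_equal(sphere_diameter_for_subtense(5, 0), 0)
  # independent inversion: root-find the subtense function numerically
  root <- uniroot(function(d) sphere_subtense(d, 4) - 10,
                  c(1e-8, 7.99), tol = 1e-12)$root
  expect_equal(sphere_diameter_for_subtense(4, 10), root, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:10) {
    d <- runif(1, 1, 11)
    s <- runif(1, 1, 60)
    expect_equal(sphere_subtense(sphere_diameter_for_subtense(d, s), d), s)
  }
})

test_that("training scenes follow the sampling protocol", {
  set.seed(7)
  big <- sample_training_scene(n_objects = 1e5)
  expect_true(all(big$distance >= 1 & big$distance <= 11))
  expect_equal(sphere_subtense(big$diameter, big$distance),
               rep(10, nrow(big)), tolerance = 1e-6)
  expect_lt(abs(sd(big$azimuth) / 45 - 1), 0.02)
  expect_lt(abs(sd(big$elevation) / 45 - 1), 0.02)
  expect_equal(nrow(sample_training_scene(n_objects = 0)), 0)
  expect_error(sample_training_scene(distance_range = c(5, 1)))
})

test_that("rendering activates exactly the units inside each silhouette", {
  g <- retinal_grid(25, 25, 70)
  expect_true(all(render_scene(scene(), eye = "left", grid = g)$values == 0))
  sc <- scene(0, 0, 4, sphere_diameter_for_subtense(4, 12))
  for (eye in c("left", "right")) {
    img <- render_scene(sc, eye = eye, grid = g)
    expect_equal(img$values, render_oracle(sc, head_pose(), eye, g))
    expect_gt(sum(img$values), 0)
  }
  # multi-sphere scene against the oracle too
  set.seed(13)
  sc3 <- sample_training_scene(3)
  img3 <- render_scene(sc3, eye = "left", grid = g)
  expect_equal(img3$values, render_oracle(sc3, head_pose(), "left", g))
})

test_that("rendering is monotone under adding spheres and mirror-symmetric on the midline", {
  g <- retinal_grid(25, 25, 70)
  set.seed(17)
  for (i in 1:5) {
    sc <- sample_training_scene(3)
    extra <- sample_training_scene(1)
    both <- scene(c(sc$azimuth, extra$azimuth), c(sc$elevation, extra$elevation),
                  c(sc$distance, extra$distance), c(sc$diameter, extra$diameter))
    a <- render_scene(sc, eye = "left", grid = g)$values
    b <- render_scene(both, eye = "left", grid = g)$values
    expect_true(all(b >= a))
  }
  sc <- scene(0, 12, 3, sphere_diameter_for_subtense(3, 14))
  l <- render_scene(sc, eye = "left", grid = g)$values
  r <- render_scene(sc, eye = "right", grid = g)$values
  expect_equal(l, r[, rev(seq_len(ncol(r)))])
})

test_that("high-elevation spheres smear across more azimuth columns", {
  g <- retinal_grid()
  cols_active <- function(elev) {
    sc <- scene(0, elev, 5, sphere_diameter_for_subtense(5, 10))
    img <- render_scene(sc, eye = "left", grid = g)
    sum(colSums(img$values) > 0)
  }
  expect_gt(cols_active(53), cols_active(0))
})

test_that("active-set azimuth centroids recover the geometric disparity", {
  g <- retinal_grid(141, 141, 35)
  sc <- scene(0, 0, 3, sphere_diameter_for_subtense(3, 10))
  centroid <- function(eye) {
    img <- render_scene(sc, eye = eye, grid = g)
    w <- colSums(img$values)
    sum(g$azimuths * w) / sum(w)
  }
  delta_geom <- binocular_view(head_pose(),
                               direction_to_point(head_direction(0, 0, 3)))$disparity
  expect_equal(centroid("right") - centroid("left"), delta_geom,
               tolerance = 0.05)
})

test_that("noise is clipped Gaussian, seed-deterministic, and off at sigma zero", {
  g <- retinal_grid(100, 100, 70)
  img <- retinal_image("left", matrix(0, 100, 100), g)
  expect_identical(add_noise(img, 0), img)
  set.seed(3); n1 <- add_noise(img, 0.1)
  set.seed(3); n2 <- add_noise(img, 0.1)
  expect_identical(n1, n2)
  # mean of max(N(0, 0.1), 0) is 0.1 / sqrt(2 pi); check within 3 s.e.
  sigma <- 0.1
  mu <- sigma / sqrt(2 * pi)
  v <- sigma^2 / 2 - mu^2
  expect_lt(abs(mean(n1$values) - mu), 3 * sqrt(v / length(n1$values)))
  expect_true(all(n1$values >= 0))
  expect_error(add_noise(img, -0.1))
})

test_that("scene labels pick the nearest visible sphere's closest output unit", {
  g <- retinal_grid()
  empty <- label_scene(scene(), g)
  expect_true(empty$is_no_action)
  expect_equal(c(empty$azimuth, empty$elevation), c(0, 0))

  # worked example scene: four spheres, nearest at (-40, 52), 3.7 cm
  dists <- c(3.7, 6.0, 7.8, 9.0)
  sc <- scene(c(-40, 31, -17, 29), c(52, 4, 0, -54), dists,
              sphere_diameter_for_subtense(dists, 10))
  lab <- label_scene(sc, g)
  # independent oracle: exhaustive search over all grid directions
  dir <- world_to_head(head_pose(), mantisstereo:::.scene_points(sc)[1, ])
  cells <- expand.grid(elevation = g$elevations, azimuth = g$azimuths)
  best <- which.min((cells$azimuth - dir$azimuth)^2 +
                      (cells$elevation - dir$elevation)^2)
  expect_equal(lab$azimuth, cells$azimuth[best])
  expect_equal(lab$elevation, cells$elevation[best])
  expect_equal(lab$azimuth, -39.2)
  expect_equal(lab$elevation, 53.2)
  expect_false(lab$is_no_action)

  # label is invariant to sphere ordering
  perm <- sample(nrow(sc))
  lab2 <- label_scene(scene(sc$azimuth[perm], sc$elevation[perm],
                            sc$distance[perm], sc$diameter[perm]), g)
  expect_equal(lab2$index, lab$index)

  # nearest sphere invisible in both eyes: the farther visible one wins
  sc2 <- scene(c(100, 10), c(0, 0), c(2, 8),
               sphere_diameter_for_subtense(c(2, 8), 10))
  for (eye in c("left", "right")) {
    p <- project_to_retina(head_pose(), eye,
                           mantisstereo:::.scene_points(sc2)[1, ])
    expect_gt(abs(p$azimuth), 70)
  }
  lab3 <- label_scene(sc2, g)
  expect_equal(lab3$azimuth, g$azimuths[which.min(abs(g$azimuths - 10))])
})

test_that("scene tables round-trip through CSV", {
  set.seed(19)
  scenes <- list(sample_training_scene(4), sample_training_scene(2))
  f <- tempfile(fileext = ".csv")
  write_scene_table(scenes, f)
  back <- read_scene_table(f)
  expect_equal(length(back), 2)
  for (i in 1:2) {
    expect_equal(as.data.frame(back[[i]]), as.data.frame(scenes[[i]]),
                 tolerance = 1e-12)
  }
})
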