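test_that("monocular preprocessing kills statics, ignores contrast sign, and matches a convolution oracle", {
  g <- strike_grid(15)
  pre <- monocular_preproc(spatial_sigma = 2, time_constant = 0.05)
  static <- array(0.7, c(15, 15, 6))
  expect_equal(preprocess(static, pre, g), array(0, c(15, 15, 6)))
  # bright-dark step and dark-bright step give identical drive
  seq1 <- array(0, c(15, 15, 6))
  seq1[4:9, 6:11, 3:6] <- 1
  seq2 <- 1 - seq1
  expect_equal(preprocess(seq1, pre, g), preprocess(seq2, pre, g))
  expect_error(preprocess(array(0, c(15, 15, 1)), pre, g), "2 frames")

  # single step edge: frame 2 drive equals a * blur(edge), with the blur
  # recomputed here by brute-force weighted sums
  edge <- array(0, c(15, 15, 2))
  edge[, 8:15, 2] <- 1
  dt <- 0.01
  got <- preprocess(edge, pre, g, frame_interval = dt)
  a <- pre$time_constant / (pre$time_constant + dt)
  sp <- diff(g$azimuths[1:2])
  ref <- matrix(0, 15, 15)
  for (i in 1:15) {
    for (j in 1:15) {
      wsum <- 0
      tot <- 0
      for (ii in 1:15) {
        for (jj in 1:15) {
          w <- exp(-((i - ii)^2) * sp^2 / (2 * pre$spatial_sigma^2)) *
            exp(-((j - jj)^2) * sp^2 / (2 * pre$spatial_sigma^2))
          wsum <- wsum + w * edge[ii, jj, 2]
          tot <- tot + w
        }
      }
      ref[i, j] <- a * wsum / tot
    }
  }
  expect_equal(got[, , 2], ref, tolerance = 1e-10)
  peak_col <- which.max(colSums(got[, , 2]))
  expect_true(peak_col >= 8)
})

test_that("the centre-surround window is size-tuned to centre-filling stimuli", {
  g <- strike_grid(41)
  rf <- centre_surround_rf("left", 0, 0, centre_radius = 5,
                           surround_radius = 10, grid = g)
  expect_gt(rf$centre_weight, 0)
  expect_lt(rf$surround_weight, 0)
  expect_equal(sum(rf$window), 0, tolerance = 1e-12)  # balanced by default
  disc_frame <- function(radius) {
    sc <- scene(0, 0, 10, 2 * 10 * sin(pmin(radius, 89) * pi / 180))
    render_scene(sc, head_pose(interocular = 0.002), eye = "left",
                 grid = g)$values
  }
  drives <- sapply(c(2, 3.5, 5, 8, 10), function(r) {
    monocular_drive(disc_frame(r), rf)
  })
  expect_equal(which.max(drives), 3)        # centre-filling disc wins
  expect_lt(drives[5], drives[3])           # intruding on the surround hurts
  expect_equal(monocular_drive(matrix(0, 41, 41), rf), 0)
  expect_error(monocular_drive(matrix(0, 5, 5), rf), "shape")
})

test_that("the binocular nonlinearity thresholds then expands", {
  sen <- strike_sensor(threshold = 1, gain = 1)
  expect_equal(binocular_response(1, 1, sen), 1)          # (2 - 1)^5
  expect_equal(binocular_response(0.4, 0.3, sen), 0)      # below threshold
  sen0 <- strike_sensor(threshold = 0, gain = 1)
  base <- binocular_response(1.3, 0.9, sen0)
  expect_equal(binocular_response(2.6, 1.8, sen0) / base, 32)
  # threshold at the single-eye maximum silences monocular input
  m <- 3.7
  sen_m <- strike_sensor(threshold = m, gain = 1)
  expect_equal(binocular_response(m, 0, sen_m), 0)
  expect_gt(binocular_response(m, m, sen_m), 0)
})

test_that("strike sampling matches the binomial expectation", {
  act <- c(0, 1, 4, 9, 2, 0.5, 7)
  gain <- 0.02
  set.seed(53)
  counts <- replicate(3000, sample_strikes(act, gain))
  p <- gain * act
  expect_true(all(p < 1))
  mu <- sum(p)
  se <- sqrt(sum(p * (1 - p)) / 3000)
  expect_lt(abs(mean(counts) - mu), 3 * se)
  expect_equal(sample_strikes(rep(0, 50), 0.5), 0)
})

test_that("stimulus builders honour their geometric contracts", {
  g <- strike_grid(31)
  disc <- build_stimulus("moving_disc", distance = 2.5, grid = g)
  v0 <- build_stimulus("vertical_disparity", distance = 2.5, offset = 0,
                       grid = g)
  expect_equal(v0$left, disc$left)
  expect_equal(v0$right, disc$right)
  expect_error(build_stimulus("ghost_pair", distance = 2.5, far_distance = 2,
                              grid = g), "unrealizable")

  # ghost pair: each eye's image equals the single-near-object image within
  # the RF centre's neighbourhood (plus a second image elsewhere)
  ghost <- build_stimulus("ghost_pair", distance = 2.5, far_distance = 5,
                          grid = g)
  sen <- default_test_sensor()
  off <- abs(sen$left_rf$centre_azimuth)
  near_mask <- function(centre_az) {
    d <- expand.grid(elevation = g$elevations, azimuth = g$azimuths)
    matrix(abs(d$azimuth - centre_az) <= 4 & abs(d$elevation) <= 6, 31, 31)
  }
  ml <- near_mask(-off)
  mr <- near_mask(off)
  mid <- floor(dim(disc$left)[3] / 2) + 1  # frames with the target centred
  for (t in mid:(mid + 4)) {
    expect_equal(ghost$left[, , t][ml], disc$left[, , t][ml])
    expect_equal(ghost$right[, , t][mr], disc$right[, , t][mr])
  }
  expect_gt(sum(ghost$left), sum(disc$left))  # the second images exist
})

test_that("the calibrated sensor is silent to monocular stimulation", {
  sen <- default_test_sensor()
  stim <- build_stimulus("moving_disc", distance = sen$preferred_distance,
                         grid = sen$grid)
  mono <- stim
  mono$right[] <- 0
  expect_equal(max(trial_activity(mono, sen)), 0)
  mono2 <- stim
  mono2$left[] <- 0
  expect_equal(max(trial_activity(mono2, sen)), 0)
  expect_gt(max(trial_activity(stim, sen)), 0)
})

test_that("size tuning is unimodal and peaks at the centre's angular size", {
  sen <- default_test_sensor()
  subtenses <- c(4, 6, 8, 10, 12, 16, 20)
  act <- sapply(subtenses, function(s) {
    stim <- build_stimulus("moving_disc", distance = sen$preferred_distance,
                           diameter = sphere_diameter_for_subtense(
                             sen$preferred_distance, s),
                           grid = sen$grid)
    mean(trial_activity(stim, sen))
  })
  peak <- which.max(act)
  expect_equal(subtenses[peak], 2 * sen$left_rf$centre_radius)
  expect_true(all(diff(act[seq_len(peak)]) >= 0))
  expect_true(all(diff(act[peak:length(act)]) <= 0))
})

test_that("activity is distance-tuned around the preferred distance", {
  sen <- default_test_sensor()
  act <- sapply(sen$preferred_distance * c(0.5, 1, 2), function(d) {
    stim <- build_stimulus("moving_disc", distance = d,
                           diameter = sphere_diameter_for_subtense(d, 10),
                           grid = sen$grid)
    mean(trial_activity(stim, sen))
  })
  expect_gt(act[2], act[1])
  expect_gt(act[2], act[3])
})

test_that("ghost pairs drive the sensor less than the matched real object", {
  sen <- default_test_sensor()
  for (fd in c(4, 5)) {
    ghost <- build_stimulus("ghost_pair", distance = sen$preferred_distance,
                            far_distance = fd, grid = sen$grid)
    real <- build_stimulus("moving_disc", distance = sen$preferred_distance,
                           grid = sen$grid)
    expect_lt(mean(trial_activity(ghost, sen)),
              mean(trial_activity(real, sen)))
  }
})

test_that("vertical disparity abolishes the response on the receptive-field scale", {
  sen <- default_test_sensor()
  offs <- c(0, 2, 4, 8, 16)
  act <- sapply(offs, function(o) {
    stim <- build_stimulus("vertical_disparity",
                           distance = sen$preferred_distance, offset = o,
                           grid = sen$grid)
    mean(trial_activity(stim, sen))
  })
  expect_gt(act[1], 0)
  expect_equal(act[length(offs)], 0)
  h <- half_response_offset(data.frame(offset = offs, mean_activity = act))
  expect_true(is.finite(h))
  expect_lt(h, 2 * sen$left_rf$surround_radius)
})

test_that("run_trial composes the deterministic trace with strike sampling", {
  sen <- default_test_sensor()
  stim <- build_stimulus("moving_disc", distance = sen$preferred_distance,
                         grid = sen$grid)
  set.seed(59)
  tr <- run_trial(stim, sen)
  expect_equal(tr$mean_activity, mean(trial_activity(stim, sen)))
  expect_equal(tr$n_frames, dim(stim$left)[3])
  blank <- stim
  blank$left[] <- 0
  blank$right[] <- 0
  expect_equal(run_trial(blank, sen)$strike_count, 0)
})
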