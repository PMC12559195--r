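test_that("velocity components align with the heading", {
  n <- 100
  t <- seq_len(n) - 1
  # male translates along +x while heading +x; female fixed far away
  tr <- make_tracks(mx = 10 * t / 50, my = rep(0, n), mh = rep(0, n),
                    fx = rep(20, n), fy = rep(0, n), fh = rep(pi, n))
  cu <- extract_cues(tr, analysis_rate_hz = 50)
  mid <- 10:90
  expect_equal(cu$male_forward_velocity[mid], rep(10, length(mid)), tolerance = 1e-9)
  expect_equal(cu$male_lateral_velocity[mid], rep(0, length(mid)), tolerance = 1e-9)
  expect_equal(cu$male_velocity[mid], rep(10, length(mid)), tolerance = 1e-9)
})

test_that("male directly behind the female reads 180 degrees, facing her 0", {
  n <- 20
  tr <- make_tracks(mx = rep(-5, n), my = rep(0, n), mh = rep(0, n),
                    fx = rep(0, n), fy = rep(0, n), fh = rep(0, n))
  cu <- extract_cues(tr, analysis_rate_hz = 50)
  expect_equal(cu$relative_angle, rep(180, n), tolerance = 1e-9)
  expect_equal(cu$relative_orientation, rep(0, n), tolerance = 1e-9)
  expect_equal(cu$distance, rep(5, n), tolerance = 1e-9)
})

test_that("circular motion matches the analytic speed and angular rate", {
  rate <- 100
  omega <- 2          # rad/s
  r <- 5              # mm
  t <- seq(0, 6, by = 1 / rate)
  ang <- omega * t
  tr <- make_tracks(mx = r * cos(ang), my = r * sin(ang), mh = ang + pi / 2,
                    fx = rep(20, length(t)), fy = rep(0, length(t)),
                    fh = rep(0, length(t)), rate_hz = rate)
  cu <- extract_cues(tr, analysis_rate_hz = rate)
  mid <- 50:550
  expect_true(all(abs(cu$male_velocity[mid] - r * omega) / (r * omega) < 0.01))
  expect_true(all(abs(cu$male_rotational_speed[mid] - omega * 180 / pi) /
                    (omega * 180 / pi) < 0.01))
})

test_that("cues are invariant to a rigid rotation of the arena", {
  tr <- generate_tracks(synth_config(duration_s = 30, seed = 5))
  th <- 0.7
  tr2 <- tr
  tr2$x_mm <- tr$x_mm * cos(th) - tr$y_mm * sin(th)
  tr2$y_mm <- tr$x_mm * sin(th) + tr$y_mm * cos(th)
  cu1 <- extract_cues(tr)
  cu2 <- extract_cues(tr2)
  for (cc in cue_names()) {
    expect_equal(cu1[[cc]], cu2[[cc]], tolerance = 1e-6, label = cc)
  }
})

test_that("downsampling 100 to 50 Hz halves the frame count", {
  tr <- generate_tracks(synth_config(duration_s = 11, seed = 2))
  n100 <- length(unique(tr$frame))
  cu <- extract_cues(tr, analysis_rate_hz = 50)
  expect_lte(abs(nrow(cu) - n100 / 2), 1)
  expect_equal(attr(cu, "rate_hz"), 50)
})

test_that("courtship mask equals a frame-by-frame geometric rederivation", {
  withr::with_seed(31, {
    n <- 1000
    fx <- runif(n, -10, 10); fy <- runif(n, -10, 10); fh <- runif(n, -pi, pi)
    mx <- fx + runif(n, -9, 9); my <- fy + runif(n, -9, 9)
  })
  tr <- make_tracks(mx, my, rep(0, n), fx, fy, fh)
  cu <- extract_cues(tr, analysis_rate_hz = 50)
  mask <- courtship_mask(cu, distance_mm = 8, angle_deg = 60)
  # oracle straight from the raw coordinates
  d <- sqrt((mx - fx)^2 + (my - fy)^2)
  bearing <- atan2(my - fy, mx - fx) - fh
  rel <- atan2(sin(bearing), cos(bearing)) * 180 / pi
  behind <- abs(ifelse(rel > 0, rel - 180, rel + 180)) <= 60
  expect_identical(mask, d < 8 & behind)
  expect_equal(courtship_index(mask), mean(d < 8 & behind))
})

test_that("courtship thresholds behave as specified", {
  n <- 10
  far <- make_tracks(rep(-10, n), rep(0, n), rep(0, n),
                     rep(0, n), rep(0, n), rep(0, n))
  expect_false(any(courtship_mask(extract_cues(far, 50), 8)))
  near <- make_tracks(rep(-5, n), rep(0, n), rep(0, n),
                      rep(0, n), rep(0, n), rep(0, n))
  expect_true(all(courtship_mask(extract_cues(near, 50), 8)))
})

test_that("validity mask excludes low confidence, close flies, copulation", {
  tr <- generate_tracks(synth_config(duration_s = 10, seed = 9,
                                     low_conf_frac = 0))
  # force one bad confidence on the male head at raw frames 100/101
  bad <- tr$fly_id == "male" & tr$part == "head" & tr$frame %in% c(100, 101)
  tr$confidence[bad] <- 0.4
  cu <- clean_kinematics(extract_cues(tr, analysis_rate_hz = 50))
  expect_false(cu$valid[51])   # analysis frame covering raw frames 100-101
  # oracle: direct logical evaluation
  ok <- cu$distance >= 1 &
    cu$conf_male_head >= 0.5 & cu$conf_male_thorax >= 0.5 &
    cu$conf_female_head >= 0.5 & cu$conf_female_thorax >= 0.5
  expect_identical(cu$valid, ok)
  # copulation cutoff
  cu2 <- clean_kinematics(extract_cues(tr, analysis_rate_hz = 50),
                          copulation_frame = 200)
  expect_true(all(!cu2$valid[cu2$frame >= 200]))
})

test_that("all-clean tracks stay fully valid", {
  n <- 50
  tr <- make_tracks(rep(-5, n), rep(0, n), rep(0, n),
                    rep(0, n), rep(0, n), rep(0, n))
  cu <- clean_kinematics(extract_cues(tr, 50))
  expect_true(all(cu$valid))
})

test_that("gaussian smoothing preserves DC, reproduces the kernel, contracts variance", {
  x <- rep(3.7, 200)
  expect_equal(smooth_series(x, 0.1, 50), x, tolerance = 1e-12)
  # impulse response is the sampled unit-mass gaussian
  imp <- c(rep(0, 100), 1, rep(0, 100))
  out <- smooth_series(imp, 0.1, 50)
  sigma <- 0.1 * 50
  r <- ceiling(4 * sigma)
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  expect_equal(out[101 + seq(-r, r)], k, tolerance = 1e-12)
  withr::with_seed(4, z <- rnorm(2000))
  expect_lt(var(smooth_series(z, 1, 50)), var(z))
  expect_error(smooth_series(z, -1, 50), class = "courtsig_config_error")
})

test_that("z-scoring normalizes over the selected frames and is invertible", {
  cu <- extract_cues(generate_tracks(synth_config(duration_s = 60, seed = 6)))
  cu <- clean_kinematics(cu)
  cu$courtship <- courtship_mask(cu, 6)
  cz <- zscore_cues(cu)
  sel <- cz$valid & cz$courtship
  for (cc in cue_names()) {
    expect_lt(abs(mean(cz[[cc]][sel])), 1e-8)
    expect_lt(abs(sd(cz[[cc]][sel]) - 1), 1e-8)
  }
  zp <- attr(cz, "zscore")
  cc <- "male_velocity"
  back <- cz[[cc]] * zp$sd[zp$cue == cc] + zp$mean[zp$cue == cc]
  expect_equal(back, cu[[cc]], tolerance = 1e-10)
})

test_that("pooling pairs tags provenance and keeps scaling per pair", {
  c1 <- zscore_cues(clean_kinematics(extract_cues(
    generate_tracks(synth_config(duration_s = 20, seed = 1)))), frames = NULL)
  c2 <- zscore_cues(clean_kinematics(extract_cues(
    generate_tracks(synth_config(duration_s = 20, seed = 2)))), frames = NULL)
  pooled <- pool_pairs(c1, c2)
  expect_equal(nrow(pooled), nrow(c1) + nrow(c2))
  expect_identical(unique(pooled$pair), c(1L, 2L))
})

test_that("missing body-part columns raise a schema error", {
  tr <- generate_tracks(synth_config(duration_s = 2, seed = 1))
  expect_error(extract_cues(dplyr::select(tr, -"confidence")),
               class = "courtsig_schema_error")
})
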